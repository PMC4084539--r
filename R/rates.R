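#' Ancestral states by weighted squared-change minimization
#'
#' Internal-node states minimizing the sum over branches of
#' (state change)^2 / (branch length), which is also the maximum-likelihood
#' reconstruction under Brownian motion with the tips fixed. This is a
#' deliberately simple, fully specified estimator used in place of
#' adaptive-peak variable-rates methods; it shares their Brownian backbone
#' but not their rate heterogeneity.
#'
#' Zero-length branches are floored at 1e-9 (with a warning) so the weighted
#' objective stays finite.
#'
#' @param tree an [ape::phylo] tree.
#' @param tip_values tips x traits matrix (rownames = tip labels) or vector.
#' @return (n_nodes) x traits matrix of internal-node states, rows named by
#'   node number (root first at `ntip + 1`).
#' @export
ancestral_states <- function(tree, tip_values) {
  if (is.null(dim(tip_values))) {
    tip_values <- matrix(tip_values, ncol = 1,
                         dimnames = list(names(tip_values), "trait"))
  }
  tip_values <- as.matrix(tip_values)
  ntip <- length(tree$tip.label)
  if (!is.null(rownames(tip_values))) {
    stopifnot(all(tree$tip.label %in% rownames(tip_values)))
    tip_values <- tip_values[tree$tip.label, , drop = FALSE]
  } else stopifnot(nrow(tip_values) == ntip)
  elen <- tree$edge.length
  if (any(elen <= 0)) {
    warning("flooring non-positive branch lengths at 1e-9")
    elen <- pmax(elen, 1e-9)
  }
  nint <- tree$Nnode
  w <- 1 / elen
  A <- matrix(0, nint, nint)                 # Laplacian over internal nodes
  b <- matrix(0, nint, ncol(tip_values))
  for (e in seq_len(nrow(tree$edge))) {
    pa <- tree$edge[e, 1] - ntip             # parent is always internal
    ch <- tree$edge[e, 2]
    A[pa, pa] <- A[pa, pa] + w[e]
    if (ch > ntip) {
      ci <- ch - ntip
      A[ci, ci] <- A[ci, ci] + w[e]
      A[pa, ci] <- A[pa, ci] - w[e]
      A[ci, pa] <- A[ci, pa] - w[e]
    } else {
      b[pa, ] <- b[pa, ] + w[e] * tip_values[ch, ]
    }
  }
  states <- solve(A, b)
  rownames(states) <- as.character(ntip + seq_len(nint))
  colnames(states) <- colnames(tip_values)
  states
}

#' Per-branch evolutionary rates
#'
#' Signed per-scalar-trait rates (state change per unit branch length;
#' positive = trait increase) or, with `per_landmark = TRUE`, the
#' non-negative per-landmark rate: the Euclidean displacement of the
#' landmark's coordinate block per unit branch length. Doubling every branch
#' length halves every rate exactly.
#'
#' @param tree an [ape::phylo] tree.
#' @param tip_values tips x traits matrix; for landmark rates the columns
#'   must be `lm<i>_<axis>` coordinates.
#' @param per_landmark logical.
#' @param states optional precomputed [ancestral_states()] output.
#' @return a `branch_rate_table`: data.frame with `parent`, `child`,
#'   `branch_length`, `terminal`, then one rate column per trait/landmark.
#' @export
branch_rates <- function(tree, tip_values, per_landmark = FALSE, states = NULL) {
  if (is.null(dim(tip_values))) {
    tip_values <- matrix(tip_values, ncol = 1,
                         dimnames = list(names(tip_values), "trait"))
  }
  tip_values <- as.matrix(tip_values)
  ntip <- length(tree$tip.label)
  if (!is.null(rownames(tip_values))) {
    tip_values <- tip_values[tree$tip.label, , drop = FALSE]
  }
  states <- states %||% ancestral_states(tree, tip_values)
  all_states <- rbind(tip_values, states)
  elen <- pmax(tree$edge.length, 1e-9)
  delta <- all_states[tree$edge[, 2], , drop = FALSE] -
    all_states[tree$edge[, 1], , drop = FALSE]
  rates <- delta / elen
  if (per_landmark) {
    cols <- colnames(tip_values)
    if (!all(grepl("^lm[0-9]+_[xyz]$", cols))) {
      stop("per-landmark rates need lm<i>_<axis> columns", call. = FALSE)
    }
    lm <- sub("_[xyz]$", "", cols)
    rates <- do.call(cbind, lapply(split(seq_along(cols), factor(lm, unique(lm))),
                                   function(ix) {
                                     sqrt(rowSums(delta[, ix, drop = FALSE]^2)) / elen
                                   }))
    colnames(rates) <- unique(lm)
  }
  out <- data.frame(parent = tree$edge[, 1], child = tree$edge[, 2],
                    branch_length = tree$edge.length,
                    terminal = tree$edge[, 2] <= ntip, rates,
                    check.names = FALSE)
  class(out) <- c("branch_rate_table", "data.frame")
  out
}

rate_columns <- function(rates) {
  setdiff(names(rates), c("parent", "child", "branch_length", "terminal"))
}

#' Summed per-landmark rates across the tree
#'
#' Sums the (absolute) per-branch relative rates for each landmark/trait
#' across all branches and, separately, across terminal branches only.
#'
#' @param rates a `branch_rate_table`.
#' @param absolute use absolute values of signed rates (default `TRUE`;
#'   per-landmark rates are already non-negative).
#' @return data.frame with `landmark`, `total_all`, `total_terminal`.
#' @export
landmark_rate_totals <- function(rates, absolute = TRUE) {
  cols <- rate_columns(rates)
  R <- as.matrix(rates[cols])
  if (absolute) R <- abs(R)
  data.frame(landmark = cols,
             total_all = colSums(R),
             total_terminal = colSums(R[rates$terminal, , drop = FALSE]),
             row.names = NULL)
}

#' Module-level comparisons of evolutionary rates
#'
#' Given per-landmark rate totals, a module partition and per-landmark
#' variances, runs the module-comparison battery:
#' a Shapiro-Wilk normality check on the rates (the gate justifying
#' nonparametric tests), Spearman correlations of rate against variance
#' (overall and per module), a Kruskal-Wallis test of rate differences
#' across modules, all pairwise Mann-Whitney comparisons with Bonferroni
#' correction over the number of module pairs, and a pooled two-group
#' comparison of strongly versus weakly integrated modules when
#' `strong_modules` is given. Modules with fewer than 3 landmarks are
#' excluded from the tests with a warning.
#'
#' @param totals output of [landmark_rate_totals()] (or a data.frame with
#'   `landmark` and a rate column named by `scope`).
#' @param partition `module_partition` over landmark ids.
#' @param landmark_variances named numeric vector (per-landmark variance
#'   across species mean shapes); optional, enables the Spearman block.
#' @param scope `"total_all"` or `"total_terminal"`.
#' @param strong_modules optional character vector of module ids treated as
#'   strongly integrated for the pooled two-group test.
#' @return list with `shapiro`, `spearman_overall`, `spearman_by_module`,
#'   `kruskal`, `pairwise` (data.frame with raw and Bonferroni p),
#'   `pooled_strong_weak`, `module_means`.
#' @export
module_rate_tests <- function(totals, partition, landmark_variances = NULL,
                              scope = c("total_all", "total_terminal"),
                              strong_modules = NULL) {
  scope <- match.arg(scope)
  rate <- stats::setNames(totals[[scope]], totals$landmark)
  mods <- unclass(partition)[names(rate)]
  if (anyNA(mods)) {
    rate <- rate[!is.na(mods)]; mods <- mods[!is.na(mods)]
  }
  counts <- table(mods)
  small <- names(counts)[counts < 3]
  if (length(small)) {
    warning("excluding modules with < 3 landmarks: ", paste(small, collapse = ", "))
    keep <- !(mods %in% small)
    rate <- rate[keep]; mods <- mods[keep]
  }
  if (length(unique(mods)) < 2) stop("need at least 2 usable modules", call. = FALSE)

  shap <- tryCatch(stats::shapiro.test(rate),
                   error = function(e) list(statistic = NA_real_, p.value = NA_real_))
  sp_all <- sp_mod <- NULL
  if (!is.null(landmark_variances)) {
    v <- landmark_variances[names(rate)]
    ct <- suppressWarnings(stats::cor.test(rate, v, method = "spearman"))
    sp_all <- data.frame(module = "all", rho = unname(ct$estimate), p = ct$p.value)
    sp_mod <- do.call(rbind, lapply(unique(mods), function(m) {
      i <- mods == m
      if (sum(i) < 3) return(NULL)
      ct <- suppressWarnings(stats::cor.test(rate[i], v[i], method = "spearman"))
      data.frame(module = m, rho = unname(ct$estimate), p = ct$p.value)
    }))
  }
  kw <- stats::kruskal.test(rate, factor(mods))
  mods_u <- sort(unique(mods))
  prs <- utils::combn(mods_u, 2)
  pairwise <- do.call(rbind, lapply(seq_len(ncol(prs)), function(j) {
    a <- prs[1, j]; b <- prs[2, j]
    wt <- suppressWarnings(stats::wilcox.test(rate[mods == a], rate[mods == b]))
    pv <- wt$p.value
    if (!is.finite(pv)) pv <- 1   # fully tied groups: no evidence of difference
    data.frame(module_a = a, module_b = b, U = unname(wt$statistic),
               p_raw = pv)
  }))
  pairwise$p_bonferroni <- stats::p.adjust(pairwise$p_raw, "bonferroni")
  pooled <- NULL
  if (!is.null(strong_modules)) {
    grp <- ifelse(mods %in% strong_modules, "strong", "weak")
    if (length(unique(grp)) == 2) {
      wt <- suppressWarnings(stats::wilcox.test(rate[grp == "strong"],
                                                rate[grp == "weak"]))
      pooled <- data.frame(U = unname(wt$statistic), p = wt$p.value,
                           mean_strong = mean(rate[grp == "strong"]),
                           mean_weak = mean(rate[grp == "weak"]))
    }
  }
  list(shapiro = shap,
       spearman_overall = sp_all, spearman_by_module = sp_mod,
       kruskal = kw, pairwise = pairwise, pooled_strong_weak = pooled,
       module_means = tapply(rate, mods, mean))
}
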