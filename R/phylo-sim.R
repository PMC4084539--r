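#' Multivariate Brownian motion on a phylogeny
#'
#' Evolves a multivariate phenotype along the tree from a zero root state.
#' Each branch adds an increment `sqrt(t) * L %*% eps`, where `L` is the
#' (lower) Cholesky factor of `Sigma`, `eps` a standard Gaussian vector and
#' `t` the branch length, so the tips are jointly Gaussian with
#' `cov(tip_a, tip_b) = (shared path length) * Sigma`. Drawing one exact
#' Gaussian increment per branch is distributionally identical to the
#' stepwise random walk along the branch.
#'
#' @param tree an [ape::phylo] tree.
#' @param Sigma positive-definite `trait_matrix` (bend first otherwise).
#' @param seed integer seed.
#' @param n_reps number of independent replicate simulations.
#' @return for `n_reps = 1` a tips x traits matrix (rownames = tip labels);
#'   otherwise a tips x traits x reps array.
#' @export
simulate_bm <- function(tree, Sigma, seed = 1L, n_reps = 1L) {
  M <- unclass(Sigma)
  Lc <- tryCatch(t(chol(M)), error = function(e) {
    stop("Sigma is not positive definite; bend_positive_definite() it first",
         call. = FALSE)
  })
  p <- ncol(M)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  edge <- tree$edge
  elen <- tree$edge.length
  # preorder traversal determined by topology alone (cladewise), so RNG
  # consumption per edge is independent of branch lengths
  ord <- ape::reorder.phylo(tree, "cladewise", index.only = TRUE)
  states <- with_seed(substream_seed(seed, "simulate_bm"), {
    eps <- array(stats::rnorm(nrow(edge) * p * n_reps),
                 c(nrow(edge), p, n_reps))
    st <- array(0, c(nnode, p, n_reps))
    for (e in ord) {
      inc <- sqrt(elen[e]) * (Lc %*% matrix(eps[e, , ], p, n_reps))
      st[edge[e, 2], , ] <- st[edge[e, 1], , ] + inc
    }
    st
  })
  tips <- states[seq_len(ntip), , , drop = FALSE]
  dimnames(tips) <- list(tree$tip.label, colnames(M), NULL)
  if (n_reps == 1L) {
    out <- tips[, , 1, drop = TRUE]
    dim(out) <- c(ntip, p)
    dimnames(out) <- list(tree$tip.label, colnames(M))
    out
  } else tips
}

#' Morphological disparity statistics for a set of tip shapes
#'
#' Euclidean distances in trait space: `mean_pairwise` (mean distance over
#' all tip pairs), `mean_to_centroid` (mean distance of tips to their grand
#' mean), and `range` (greatest distance between any pair of tips).
#'
#' @param tips tips x traits matrix.
#' @return named numeric vector with the three statistics.
#' @export
disparity_stats <- function(tips) {
  tips <- as.matrix(tips)
  if (nrow(tips) < 2) stop("need at least 2 tips", call. = FALSE)
  d <- stats::dist(tips)
  cen <- colMeans(tips)
  c(mean_pairwise = mean(d),
    mean_to_centroid = mean(sqrt(rowSums(sweep(tips, 2, cen)^2))),
    range = max(d))
}

#' Paired correlated/uncorrelated disparity experiment
#'
#' Runs `n_reps` Brownian-motion simulations with `Sigma` (correlated arm)
#' and `n_reps` with `decorrelate(Sigma)` (uncorrelated arm; same diagonal,
#' zero covariances), using independent draws in the two arms, and reports
#' the mean of each disparity statistic per arm plus the corr/uncorr ratios.
#'
#' @param tree an [ape::phylo] tree.
#' @param Sigma positive-definite `trait_matrix`.
#' @param n_reps replicates per arm (the classic design uses 1000).
#' @param seed integer seed.
#' @return list with `summary` (data.frame: statistic, mean_corr,
#'   mean_uncorr, ratio, se_ratio) and `per_rep` (data.frame of all runs).
#' @export
paired_disparity_experiment <- function(tree, Sigma, n_reps = 1000L, seed = 1L) {
  arms <- list(corr = Sigma, uncorr = decorrelate(Sigma))
  per <- lapply(names(arms), function(a) {
    tips <- simulate_bm(tree, arms[[a]], n_reps = n_reps,
                        seed = substream_seed(seed, paste0("disparity:", a)))
    stats_mat <- t(apply(tips, 3, disparity_stats))
    data.frame(arm = a, rep = seq_len(n_reps), stats_mat)
  })
  per <- do.call(rbind, per)
  stat_names <- c("mean_pairwise", "mean_to_centroid", "range")
  summ <- do.call(rbind, lapply(stat_names, function(s) {
    xc <- per[per$arm == "corr", s]; xu <- per[per$arm == "uncorr", s]
    mc <- mean(xc); mu <- mean(xu)
    ratio <- mc / mu
    # delta-method standard error of the ratio of two independent means
    se <- ratio * sqrt(stats::var(xc) / (n_reps * mc^2) +
                         stats::var(xu) / (n_reps * mu^2))
    data.frame(statistic = s, mean_corr = mc, mean_uncorr = mu,
               ratio = ratio, se_ratio = se)
  }))
  rownames(summ) <- NULL
  list(summary = summ, per_rep = per)
}

#' Single-lineage divergence trajectories
#'
#' Random walk of one lineage in discrete unit-time steps (increment
#' `L %*% eps` per step) tracking the Euclidean distance from the starting
#' phenotype at every step, for both the supplied matrix and any comparison
#' the caller makes (run twice with [decorrelate()] to reproduce the
#' correlated-vs-uncorrelated fan plots). The expected squared distance is
#' `t * trace(Sigma)` at step `t` regardless of the correlations; the
#' correlations widen the spread of the distances around that mean.
#'
#' @param Sigma positive-definite `trait_matrix`.
#' @param n_steps number of steps.
#' @param n_reps number of independent lineages.
#' @param seed integer seed.
#' @param probs quantiles summarized per step.
#' @return list with `distances` (reps x steps matrix) and `quantiles`
#'   (steps x length(probs) matrix).
#' @export
divergence_trajectories <- function(Sigma, n_steps, n_reps = 1000L, seed = 1L,
                                    probs = c(0.025, 0.25, 0.5, 0.75, 0.975)) {
  p <- nrow(Sigma)
  if (n_steps < 0) stop("n_steps must be >= 0", call. = FALSE)
  Lc <- t(chol(unclass(Sigma)))
  D <- with_seed(substream_seed(seed, "divergence_trajectories"), {
    out <- matrix(0, n_reps, max(n_steps, 0L))
    if (n_steps > 0) {
      for (r in seq_len(n_reps)) {
        inc <- Lc %*% matrix(stats::rnorm(p * n_steps), p, n_steps)
        pos <- apply(inc, 1, cumsum)          # steps x traits
        out[r, ] <- sqrt(rowSums(pos^2))
      }
    }
    out
  })
  q <- if (n_steps > 0) {
    t(apply(D, 2, stats::quantile, probs = probs))
  } else matrix(numeric(0), 0, length(probs))
  list(distances = D, quantiles = q)
}

#' Scan of range-disparity inflation against integration
#'
#' Runs the paired disparity experiment for each matrix and relates the
#' range ratio (correlated / uncorrelated) to the matrix's relative
#' eigenvalue standard deviation by Spearman rank correlation (exact
#' permutation p-value for ten or fewer matrices).
#'
#' @param matrices list of `trait_matrix` objects.
#' @param tree an [ape::phylo] tree.
#' @param n_reps replicates per arm per matrix.
#' @param seed integer seed.
#' @return list with `table` (per-matrix rel_sd, r2 and the three ratios)
#'   and `spearman` (list: rho, p; `NA` with a warning under ties).
#' @export
integration_vs_range_scan <- function(matrices, tree, n_reps = 1000L, seed = 1L) {
  if (length(matrices) < 3) stop("need at least 3 matrices", call. = FALSE)
  ids <- names(matrices) %||% paste0("m", seq_along(matrices))
  rows <- lapply(seq_along(matrices), function(i) {
    M <- bend_positive_definite(matrices[[i]])
    ex <- paired_disparity_experiment(tree, M, n_reps = n_reps,
                                      seed = substream_seed(seed, paste0("scan:", i)))
    r <- stats::setNames(ex$summary$ratio, ex$summary$statistic)
    data.frame(matrix = ids[i], rel_sd = rel_eigen_sd(M),
               r2 = mean_squared_correlation(M),
               mpd_ratio = r[["mean_to_centroid"]],
               mean_pairwise_ratio = r[["mean_pairwise"]],
               range_ratio = r[["range"]])
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  sp <- if (length(unique(tab$rel_sd)) < 2 || length(unique(tab$range_ratio)) < 2) {
    warning("ties leave the Spearman correlation undefined")
    list(rho = NA_real_, p = NA_real_)
  } else {
    ct <- suppressWarnings(stats::cor.test(tab$rel_sd, tab$range_ratio,
                                           method = "spearman",
                                           exact = nrow(tab) <= 10))
    list(rho = unname(ct$estimate), p = ct$p.value)
  }
  list(table = tab, spearman = sp)
}
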