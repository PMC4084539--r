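#' Phylogenetic GLS correlation between two variables
#'
#' Correlation of `y` with `x` under a Brownian-motion residual covariance
#' derived from the tree (V[i, j] = shared root-to-tip path length; Pagel's
#' lambda fixed at 1). The coefficient is the GLS correlation: cross-products
#' of GLS-mean-centered variables weighted by V^-1, standardized by the GLS
#' variances. The p-value comes from the t distribution with n - 2 degrees of
#' freedom. On a star phylogeny this reduces exactly to the ordinary Pearson
#' correlation.
#'
#' @param x,y numeric vectors named by tree tip labels (or in tip order).
#' @param tree an [ape::phylo] tree; tips without data are pruned.
#' @return list with `coefficient`, `p`, `n`.
#' @export
pgls_corr <- function(x, y, tree) {
  if (!is.null(names(x))) {
    common <- intersect(tree$tip.label, names(x))
    if (length(common) < 4) stop("need at least 4 matched taxa", call. = FALSE)
    missing_tips <- setdiff(names(x), tree$tip.label)
    if (length(missing_tips)) {
      stop("rows absent from tree: ", paste(missing_tips, collapse = ", "),
           call. = FALSE)
    }
    if (length(common) < length(tree$tip.label)) {
      tree <- ape::drop.tip(tree, setdiff(tree$tip.label, common))
    }
    x <- x[tree$tip.label]; y <- y[tree$tip.label]
  } else if (length(x) != length(tree$tip.label)) {
    stop("unnamed data must match the number of tips", call. = FALSE)
  }
  n <- length(x)
  if (n < 4) stop("need at least 4 taxa", call. = FALSE)
  V <- ape::vcv(tree)
  Vi <- solve(V)
  one <- rep(1, n)
  denom <- sum(Vi %*% one * one)
  mx <- sum(Vi %*% x * one) / denom
  my <- sum(Vi %*% y * one) / denom
  xs <- x - mx; ys <- y - my
  sxx <- drop(crossprod(xs, Vi %*% xs))
  syy <- drop(crossprod(ys, Vi %*% ys))
  sxy <- drop(crossprod(xs, Vi %*% ys))
  if (sxx <= 0 || syy <= 0) stop("zero GLS variance", call. = FALSE)
  r <- sxy / sqrt(sxx * syy)
  r <- max(-1, min(1, r))
  tt <- if (abs(r) >= 1) Inf else r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  list(coefficient = r, p = p, n = n)
}

#' Raw and PGLS correlation table for a metric panel
#'
#' Square table over the panel columns with ordinary Pearson correlations in
#' the lower triangle and PGLS-corrected correlations (Brownian covariance
#' from `tree`) in the upper triangle; the diagonal is `NA`. A companion
#' logical matrix flags entries significant at `alpha`.
#'
#' @param panel data.frame or matrix: rows = taxa/matrix ids (rownames must
#'   match tree tips for the PGLS half), columns = metrics.
#' @param tree an [ape::phylo] tree.
#' @param alpha significance threshold for the flag matrix (default 0.01).
#' @return list with `table` (numeric matrix), `significant` (logical
#'   matrix), `p` (p-value matrix, same layout).
#' @export
correlation_table <- function(panel, tree, alpha = 0.01) {
  panel <- as.matrix(panel)
  if (anyNA(panel)) stop("panel must be complete", call. = FALSE)
  k <- ncol(panel)
  nm <- colnames(panel) %||% paste0("v", seq_len(k))
  tab <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  pm <- tab
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    ct <- stats::cor.test(panel[, i], panel[, j])
    tab[j, i] <- unname(ct$estimate); pm[j, i] <- ct$p.value       # raw, lower
    g <- pgls_corr(stats::setNames(panel[, i], rownames(panel)),
                   stats::setNames(panel[, j], rownames(panel)), tree)
    tab[i, j] <- g$coefficient; pm[i, j] <- g$p                    # PGLS, upper
  }
  list(table = tab, significant = pm < alpha, p = pm)
}
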