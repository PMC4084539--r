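#' Trait covariance / correlation matrices
#'
#' A `trait_matrix` is a labelled square symmetric matrix over traits (either
#' individual shape coordinates or other scalar traits), tagged as a
#' covariance or a correlation matrix, optionally carrying a module partition
#' (a named map trait -> module). It is the G-matrix analogue that the
#' skewers and Brownian-motion machinery consume.
#'
#' @param values square symmetric numeric matrix.
#' @param kind `"covariance"` or `"correlation"`.
#' @param labels trait labels; defaults to existing dimnames or `t1..tN`.
#' @param partition optional named character vector mapping trait label to
#'   module id (names must be a permutation-free subset of `labels`).
#' @return a `trait_matrix` object (a numeric matrix with attributes).
#' @export
trait_matrix <- function(values, kind = c("covariance", "correlation"),
                         labels = NULL, partition = NULL) {
  kind <- match.arg(kind)
  check_square_symmetric(values, what = "trait matrix")
  n <- nrow(values)
  if (is.null(labels)) {
    labels <- rownames(values) %||% paste0("t", seq_len(n))
  }
  stopifnot(length(labels) == n, !anyDuplicated(labels))
  values <- (values + t(values)) / 2
  dimnames(values) <- list(labels, labels)
  if (kind == "correlation") {
    if (max(abs(diag(values) - 1)) > 1e-8) {
      stop("correlation matrix must have unit diagonal", call. = FALSE)
    }
    diag(values) <- 1
    if (max(abs(values[upper.tri(values)])) > 1 + 1e-8) {
      stop("correlation entries must lie in [-1, 1]", call. = FALSE)
    }
  }
  if (!is.null(partition)) {
    stopifnot(!is.null(names(partition)), all(names(partition) %in% labels))
  }
  structure(values,
            kind = kind, partition = partition,
            class = c("trait_matrix", "matrix", "array"))
}

#' @export
print.trait_matrix <- function(x, ...) {
  cat(sprintf("<trait_matrix> %d x %d %s matrix\n", nrow(x), ncol(x),
              attr(x, "kind")))
  if (!is.null(attr(x, "partition"))) {
    cat("  partition:", paste(unique(attr(x, "partition")), collapse = ", "), "\n")
  }
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x))), drop = FALSE])
  if (nrow(x) > 6L) cat("  ...\n")
  invisible(x)
}

tm_kind <- function(M) attr(M, "kind") %||% "covariance"
tm_partition <- function(M) attr(M, "partition")

#' Equicorrelation matrix
#'
#' All off-diagonal correlations equal to `r`. Positive definite exactly when
#' `-1/(n-1) < r < 1`; eigenvalues are `1 + (n-1) r` (once) and `1 - r`
#' (n-1 times), so its relative eigenvalue standard deviation equals `|r|`.
#'
#' @param n_traits number of traits (>= 2).
#' @param r common correlation.
#' @return a correlation `trait_matrix`.
#' @export
uniform_correlation_matrix <- function(n_traits, r) {
  stopifnot(n_traits >= 2)
  lo <- -1 / (n_traits - 1)
  if (r <= lo || r >= 1) {
    stop(sprintf(
      "r = %g is outside the positive-definite range (%g, 1) for %d traits",
      r, lo, n_traits), call. = FALSE)
  }
  M <- matrix(r, n_traits, n_traits)
  diag(M) <- 1
  trait_matrix(M, kind = "correlation")
}

#' Block-modular correlation matrix
#'
#' Within-block off-diagonals set per block, all between-block entries set to
#' `rho_between`; the block membership is recorded as the matrix's module
#' partition. Positive semi-definiteness is validated by eigendecomposition.
#'
#' @param block_sizes integer vector of block sizes.
#' @param rho_within scalar or per-block vector of within-block correlations.
#' @param rho_between between-block correlation (default 0).
#' @param module_names optional block names (default `M1..Mk`).
#' @return a correlation `trait_matrix` with a partition attribute.
#' @export
block_correlation_matrix <- function(block_sizes, rho_within, rho_between = 0,
                                     module_names = NULL) {
  stopifnot(all(block_sizes >= 1), length(block_sizes) >= 1)
  k <- length(block_sizes)
  rho_within <- rep_len(rho_within, k)
  n <- sum(block_sizes)
  module_names <- module_names %||% paste0("M", seq_len(k))
  block_of <- rep(module_names, times = block_sizes)
  M <- matrix(rho_between, n, n)
  idx <- split(seq_len(n), factor(block_of, levels = module_names))
  for (b in seq_len(k)) M[idx[[b]], idx[[b]]] <- rho_within[b]
  diag(M) <- 1
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    stop(sprintf(
      "requested block structure is not positive semi-definite (smallest eigenvalue %.3g)",
      min(ev)), call. = FALSE)
  }
  labels <- paste0("t", seq_len(n))
  trait_matrix(M, kind = "correlation", labels = labels,
               partition = stats::setNames(block_of, labels))
}

#' Ladder of correlation matrices spanning a range of integration
#'
#' Returns matrices whose relative eigenvalue standard deviations are evenly
#' spaced over `lambda_range`. The default construction is equicorrelation,
#' for which the index equals the common correlation exactly; a single-factor
#' construction with random loadings (scaled by bisection to hit each target)
#' is available for structural diversity.
#'
#' @param n_matrices number of matrices (>= 2).
#' @param n_traits traits per matrix.
#' @param lambda_range numeric `c(low, high)` with `0 < low <= high < 1`.
#' @param seed integer seed (used by the factor construction).
#' @param method `"equicorrelation"` or `"factor"`.
#' @return list of correlation `trait_matrix` objects, ordered by target.
#' @export
integration_ladder <- function(n_matrices, n_traits, lambda_range,
                               seed = 1L, method = c("equicorrelation", "factor")) {
  method <- match.arg(method)
  if (n_matrices < 2) stop("n_matrices must be at least 2", call. = FALSE)
  stopifnot(length(lambda_range) == 2, lambda_range[1] > 0,
            lambda_range[2] < 1, lambda_range[1] <= lambda_range[2])
  targets <- seq(lambda_range[1], lambda_range[2], length.out = n_matrices)
  if (method == "equicorrelation") {
    return(lapply(targets, function(r) uniform_correlation_matrix(n_traits, r)))
  }
  with_seed(substream_seed(seed, "integration_ladder"), {
    lapply(targets, function(target) {
      a <- stats::runif(n_traits, 0.3, 1)
      build <- function(w) {
        M <- w * tcrossprod(a)
        diag(M) <- 1
        M
      }
      f <- function(w) rel_eigen_sd(trait_matrix(build(w), "correlation")) - target
      w_hi <- 0.999 / max(a)^2
      w <- stats::uniroot(f, c(1e-9, w_hi), tol = 1e-12)$root
      trait_matrix(build(w), kind = "correlation")
    })
  })
}

#' Bend a singular matrix to positive definiteness
#'
#' Eigenvalues below `floor_frac` times the largest eigenvalue are raised to
#' that floor and the matrix is recomposed from the original eigenvectors
#' (which are preserved; no eigenvalue ever decreases). A correlation matrix
#' is rescaled afterwards so its diagonal returns to exactly 1.
#'
#' @param M a `trait_matrix` (or plain symmetric matrix).
#' @param floor_frac eigenvalue floor as a fraction of the largest eigenvalue.
#' @return a positive-definite `trait_matrix` of the same kind.
#' @export
bend_positive_definite <- function(M, floor_frac = 1e-8) {
  check_square_symmetric(M, tol = 1e-8, what = "matrix to bend")
  kind <- tm_kind(M)
  part <- tm_partition(M)
  labels <- rownames(M) %||% paste0("t", seq_len(nrow(M)))
  e <- eigen(M, symmetric = TRUE)
  lam_max <- max(e$values)
  if (lam_max <= 0) stop("cannot bend a matrix with no positive eigenvalue", call. = FALSE)
  floor_val <- floor_frac * lam_max
  if (min(e$values) >= floor_val) {
    return(trait_matrix(unclass(M), kind = kind, labels = labels, partition = part))
  }
  lam <- pmax(e$values, floor_val)
  out <- e$vectors %*% (lam * t(e$vectors))
  out <- (out + t(out)) / 2
  if (kind == "correlation") out <- stats::cov2cor(out)
  trait_matrix(out, kind = kind, labels = labels, partition = part)
}

#' Strip off-diagonal covariances
#'
#' Returns the matrix used for the "uncorrelated evolution" arm of the
#' Brownian-motion experiments: same diagonal (so per-trait variances, and
#' hence the trace, are preserved exactly), zero everywhere else.
#'
#' @param Sigma a `trait_matrix`.
#' @return a diagonal `trait_matrix` of the same kind.
#' @export
decorrelate <- function(Sigma) {
  out <- diag(diag(unclass(Sigma)), nrow(Sigma))
  trait_matrix(out, kind = tm_kind(Sigma),
               labels = rownames(Sigma) %||% paste0("t", seq_len(nrow(Sigma))),
               partition = tm_partition(Sigma))
}

#' Standardize a covariance trait matrix to correlation
#' @param M a `trait_matrix`.
#' @return a correlation `trait_matrix`.
#' @export
as_correlation <- function(M) {
  if (tm_kind(M) == "correlation") return(M)
  if (any(diag(M) <= 0)) stop("zero-variance trait: cannot standardize", call. = FALSE)
  trait_matrix(stats::cov2cor(unclass(M)), kind = "correlation",
               labels = rownames(M), partition = tm_partition(M))
}
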