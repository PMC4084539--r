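#' Draw random unit-length selection vectors
#'
#' Uniform on the unit sphere: independent standard Gaussians normalized to
#' unit Euclidean norm. One vector per row.
#'
#' @param n_traits vector dimension (>= 2).
#' @param n number of vectors.
#' @param seed integer seed.
#' @return n x n_traits matrix with unit-norm rows.
#' @export
draw_selection_vectors <- function(n_traits, n, seed = 1L) {
  stopifnot(n_traits >= 2, n >= 1)
  with_seed(substream_seed(seed, "draw_selection_vectors"), {
    B <- matrix(stats::rnorm(n * n_traits), n, n_traits)
    B / sqrt(rowSums(B^2))
  })
}

#' Selection-response metrics for one skewer
#'
#' Given a G-matrix analogue and a unit selection vector beta, the response
#' is `z = G beta` and the metrics are:
#' respondability `||z||` (magnitude of response in any direction),
#' evolvability `beta' z` (response along the direction of selection),
#' conditional evolvability `1 / (beta' G^-1 beta)` (response along selection
#' when all other directions are held by stabilizing selection),
#' flexibility `cos(beta, z)` (alignment of response with selection), and
#' constraint `|cos(z, g_max)|` (alignment of response with the leading
#' eigenvector of G). Under a leading-eigenvalue tie (e.g. the identity
#' matrix) the leading eigenvector is undefined and constraint is `NA`.
#'
#' @param G a positive-definite `trait_matrix` (bend first if singular).
#' @param beta unit-norm selection vector.
#' @return named numeric vector with the five metrics.
#' @export
skewer_metrics <- function(G, beta) {
  pre <- skewer_prep(G)
  skewer_metrics_prepped(pre, matrix(beta, nrow = 1))[1, ]
}

# factor G once; reused across many skewers
skewer_prep <- function(G) {
  M <- unclass(G)
  e <- eigen(M, symmetric = TRUE)
  if (min(e$values) <= 0) {
    stop("G is singular or indefinite; apply bend_positive_definite() first",
         call. = FALSE)
  }
  cond <- max(e$values) / min(e$values)
  inv_vals <- if (cond > 1e12) {
    ifelse(e$values > max(e$values) * 1e-12, 1 / e$values, 0)  # pseudo-inverse
  } else 1 / e$values
  g_max <- if (length(e$values) > 1 &&
               (e$values[1] - e$values[2]) <= 1e-12 * e$values[1]) {
    NULL  # tied leading eigenvalues: constraint undefined
  } else e$vectors[, 1]
  list(M = M, vectors = e$vectors, values = e$values, inv_vals = inv_vals,
       g_max = g_max)
}

skewer_metrics_prepped <- function(pre, B) {
  Z <- B %*% pre$M                                   # rows: responses
  resp <- sqrt(rowSums(Z^2))
  evol <- rowSums(B * Z)
  W <- B %*% pre$vectors
  cond_evol <- 1 / rowSums(sweep(W^2, 2, pre$inv_vals, "*"))
  flex <- evol / resp
  constr <- if (is.null(pre$g_max)) rep(NA_real_, nrow(B)) else {
    abs(Z %*% pre$g_max) / resp
  }
  cbind(respondability = resp, evolvability = evol,
        conditional_evolvability = cond_evol, flexibility = flex,
        constraint = as.vector(constr))
}

#' Random-skewers simulation
#'
#' Probes a G-matrix with `n` random unit selection vectors and returns the
#' per-skewer metrics plus their means. For every skewer the Cauchy-Schwarz
#' chain `conditional_evolvability <= evolvability <= respondability` holds.
#'
#' @param G a positive-definite `trait_matrix`.
#' @param n number of skewers (the classic design uses 1000).
#' @param seed integer seed.
#' @return list with `records` (n x 5 matrix) and `means` (named vector).
#' @export
random_skewers <- function(G, n = 1000L, seed = 1L) {
  pre <- skewer_prep(G)
  B <- draw_selection_vectors(nrow(G), n, seed = seed)
  records <- skewer_metrics_prepped(pre, B)
  list(records = records, means = colMeans(records))
}

#' Skewer panel summary across many matrices
#'
#' One row per matrix: the two integration indices (relative eigenvalue
#' standard deviation and mean squared correlation) and the mean of each
#' skewer metric over `n` skewers. This is the machinery behind
#' correlating integration with response to selection across a panel of
#' species matrices. Matrices that are singular are bent first; a matrix
#' that still fails is dropped with a warning.
#'
#' @param matrices list of `trait_matrix` objects (named or not).
#' @param n skewers per matrix.
#' @param seed integer seed.
#' @param shared_skewers if `TRUE` (default), the same skewer set is applied
#'   to every matrix of a given trait dimension (common random numbers):
#'   identical matrices then produce identical rows, and cross-matrix
#'   contrasts in respondability, flexibility and constraint are not blurred
#'   by skewer sampling noise. Use `FALSE` to mirror a design where every
#'   dataset is probed by its own independent skewer draw; this is the right
#'   mode for judging whether a metric whose spherical expectation is flat
#'   (such as evolvability on correlation matrices) shows any relationship
#'   with integration, since common random numbers would turn the shared
#'   Monte-Carlo error into a spurious perfect correlation.
#' @return data.frame with columns `matrix`, `rel_sd`, `r2`, and the five
#'   skewer-metric means.
#' @export
skewer_panel_summary <- function(matrices, n = 1000L, seed = 1L,
                                 shared_skewers = TRUE) {
  ids <- names(matrices) %||% paste0("m", seq_along(matrices))
  skewer_sets <- new.env(parent = emptyenv())
  rows <- lapply(seq_along(matrices), function(i) {
    M <- matrices[[i]]
    M <- tryCatch(bend_positive_definite(M), error = function(e) NULL)
    if (is.null(M)) {
      warning("dropping matrix ", ids[i], ": not positive definite after bending")
      return(NULL)
    }
    key <- if (shared_skewers) as.character(nrow(M)) else
      paste0(nrow(M), ":", i)
    if (is.null(skewer_sets[[key]])) {
      skewer_sets[[key]] <- draw_selection_vectors(
        nrow(M), n, seed = substream_seed(seed, paste0("panel_dim:", key)))
    }
    rec <- skewer_metrics_prepped(skewer_prep(M), skewer_sets[[key]])
    data.frame(matrix = ids[i], rel_sd = rel_eigen_sd(M),
               r2 = mean_squared_correlation(M), t(colMeans(rec)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
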