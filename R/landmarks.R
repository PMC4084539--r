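#' Generalized Procrustes alignment
#'
#' Iterative superimposition removing translation (centering), size (unit
#' centroid size) and rotation (no reflections) from a set of landmark
#' configurations. The consensus is re-estimated as the coordinate-wise mean
#' of aligned configurations until it changes by less than `tol` (Frobenius
#' norm). No tangent-space projection is applied by default; a projection
#' flag exists for users who want Rohlf-style orthogonal projection.
#'
#' @param specimens specimen table (see [sample_specimens()]) or an
#'   `n x L x D` array of landmark coordinates.
#' @param tol convergence tolerance on the consensus update.
#' @param max_iter maximum number of alignment sweeps.
#' @param project logical; project aligned shapes onto the tangent plane at
#'   the consensus (default `FALSE`).
#' @return object of class `aligned_shapes`: list with `coords`
#'   (n x L x D Procrustes coordinates), `centroid_size` (original units),
#'   `consensus` (L x D), `species`, `specimen`, `iterations`.
#' @export
gpa_align <- function(specimens, tol = 1e-10, max_iter = 1000L, project = FALSE) {
  if (is.data.frame(specimens)) {
    parts <- specimens_to_array(specimens)
  } else if (is.array(specimens) && length(dim(specimens)) == 3) {
    parts <- list(coords = specimens,
                  species = dimnames(specimens)[[1]] %||% rep("sp1", dim(specimens)[1]),
                  specimen = dimnames(specimens)[[1]] %||% paste0("s", seq_len(dim(specimens)[1])))
  } else stop("specimens must be a specimen table or an n x L x D array", call. = FALSE)
  X <- parts$coords
  n <- dim(X)[1]; L <- dim(X)[2]; D <- dim(X)[3]
  if (n < 2) stop("need at least 2 specimens to align", call. = FALSE)

  confs <- lapply(seq_len(n), function(i) matrix(X[i, , ], L, D))
  csize <- numeric(n)
  for (i in seq_len(n)) {
    ci <- confs[[i]]
    ci <- sweep(ci, 2, colMeans(ci))
    cs <- sqrt(sum(ci^2))
    if (cs < 1e-12) stop("degenerate configuration: all landmarks coincide", call. = FALSE)
    csize[i] <- cs
    confs[[i]] <- ci / cs
  }

  rotate_onto <- function(A, B) {
    # optimal rotation (det +1) of A onto B
    s <- svd(crossprod(A, B))
    d <- sign(det(s$u %*% t(s$v)))
    S <- diag(c(rep(1, D - 1), d), D)
    A %*% (s$u %*% S %*% t(s$v))
  }

  consensus <- confs[[1]]
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    confs <- lapply(confs, rotate_onto, B = consensus)
    new_consensus <- Reduce(`+`, confs) / n
    new_consensus <- new_consensus / sqrt(sum(new_consensus^2))
    delta <- sqrt(sum((new_consensus - consensus)^2))
    consensus <- new_consensus
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    stop(sprintf("GPA did not converge in %d iterations", max_iter), call. = FALSE)
  }
  # final sweep so every configuration is optimally rotated to the consensus
  confs <- lapply(confs, rotate_onto, B = consensus)
  consensus <- Reduce(`+`, confs) / n

  # canonical frame: principal axes of the consensus with a deterministic
  # sign convention, so the result does not depend on specimen order
  sv <- svd(consensus)
  Q <- sv$v
  if (det(Q) < 0) Q[, D] <- -Q[, D]
  rc <- consensus %*% Q
  s <- vapply(seq_len(D), function(d) {
    v <- rc[, d]; sign(v[which.max(abs(v))])
  }, numeric(1))
  s[s == 0] <- 1
  if (prod(s) < 0) s[D] <- -s[D]
  Q <- Q %*% diag(s, D)
  confs <- lapply(confs, function(ci) ci %*% Q)
  consensus <- consensus %*% Q

  if (project) {
    flat <- t(vapply(confs, as.vector, numeric(L * D)))
    m <- as.vector(consensus) / sqrt(sum(consensus^2))
    flat <- flat - (flat %*% m) %*% t(m) + rep(1, n) %*% t(m)
    confs <- lapply(seq_len(n), function(i) matrix(flat[i, ], L, D))
  }

  coords <- array(0, c(n, L, D),
                  dimnames = list(parts$specimen, paste0("lm", seq_len(L)),
                                  c("x", "y", "z")[seq_len(D)]))
  for (i in seq_len(n)) coords[i, , ] <- confs[[i]]
  structure(list(coords = coords, centroid_size = csize, consensus = consensus,
                 species = parts$species, specimen = parts$specimen,
                 iterations = iter),
            class = "aligned_shapes")
}

#' @export
print.aligned_shapes <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("<aligned_shapes> %d specimens, %d landmarks, %dD (GPA, %d iterations)\n",
              d[1], d[2], d[3], x$iterations))
  invisible(x)
}

#' Procrustes distance between two aligned configurations
#' @param a,b L x D matrices (already aligned).
#' @return Euclidean (tangent-space) distance.
#' @export
procrustes_distance <- function(a, b) sqrt(sum((a - b)^2))

residual_matrix <- function(aligned, residual_from = c("species-mean", "grand-mean")) {
  residual_from <- match.arg(residual_from)
  flat <- flatten_landmarks(aligned$coords)
  if (residual_from == "grand-mean") {
    return(sweep(flat, 2, colMeans(flat)))
  }
  sp <- aligned$species
  for (s in unique(sp)) {
    i <- which(sp == s)
    flat[i, ] <- sweep(flat[i, , drop = FALSE], 2,
                       colMeans(flat[i, , drop = FALSE]))
  }
  flat
}

#' Pooled within-species covariance matrix
#'
#' Covariance of deviations from each species' own mean shape, pooled across
#' species with weights equal to the within-species degrees of freedom
#' (n_i - 1). Species represented by a single specimen carry no information
#' about within-species covariance and are dropped with a warning.
#'
#' @param aligned an `aligned_shapes` object (or any specimen x trait matrix
#'   if `species` is given).
#' @param species optional species labels overriding those stored in
#'   `aligned`.
#' @return a covariance `trait_matrix` over coordinate-level traits.
#' @export
pooled_within_species_cov <- function(aligned, species = NULL) {
  if (inherits(aligned, "aligned_shapes")) {
    flat <- flatten_landmarks(aligned$coords)
    species <- species %||% aligned$species
  } else {
    flat <- as.matrix(aligned)
    if (is.null(species)) stop("species labels required", call. = FALSE)
  }
  counts <- table(species)
  drop <- names(counts)[counts < 2]
  if (length(drop)) {
    warning("dropping species with a single specimen: ",
            paste(drop, collapse = ", "))
  }
  keep <- !(species %in% drop)
  flat <- flat[keep, , drop = FALSE]
  species <- species[keep]
  groups <- split(seq_len(nrow(flat)), species)
  if (length(groups) < 1 || nrow(flat) - length(groups) < 1) {
    stop("fewer than 2 usable specimen-species groups", call. = FALSE)
  }
  p <- ncol(flat)
  SS <- matrix(0, p, p)
  df <- 0
  for (i in groups) {
    d <- sweep(flat[i, , drop = FALSE], 2, colMeans(flat[i, , drop = FALSE]))
    SS <- SS + crossprod(d)
    df <- df + length(i) - 1
  }
  trait_matrix(SS / df, kind = "covariance", labels = colnames(flat))
}

#' Landmark-level congruence-coefficient correlation matrix
#'
#' Scale-free covariation between landmarks: entry (i, j) is the trace of the
#' D x D cross-covariance block between landmarks i and j divided by the
#' geometric mean of the traces of their within-landmark blocks, computed on
#' residuals from the species means (default) or the grand mean. The diagonal
#' is 1 by construction. A vectorized-Pearson alternative (correlation of the
#' stacked coordinate deviations) is available via `method`.
#'
#' @param aligned an `aligned_shapes` object.
#' @param residual_from `"species-mean"` or `"grand-mean"`.
#' @param method `"congruence"` (trace convention) or `"pearson"`.
#' @return an L x L correlation `trait_matrix` labelled `lm1..lmL`.
#' @export
congruence_correlation_matrix <- function(aligned,
                                          residual_from = c("species-mean", "grand-mean"),
                                          method = c("congruence", "pearson")) {
  method <- match.arg(method)
  residual_from <- match.arg(residual_from)
  n <- dim(aligned$coords)[1]; L <- dim(aligned$coords)[2]; D <- dim(aligned$coords)[3]
  if (n < 3) stop("need at least 3 specimens", call. = FALSE)
  R <- residual_matrix(aligned, residual_from)
  C <- stats::cov(R)
  block <- function(i) ((i - 1) * D + 1):(i * D)
  within_tr <- vapply(seq_len(L), function(i) sum(diag(C[block(i), block(i), drop = FALSE])),
                      numeric(1))
  zero <- which(within_tr <= 1e-14)
  if (length(zero)) {
    stop("zero-variance landmark(s): ", paste0("lm", zero, collapse = ", "),
         call. = FALSE)
  }
  out <- matrix(1, L, L)
  for (i in seq_len(L - 1)) for (j in (i + 1):L) {
    if (method == "congruence") {
      v <- sum(diag(C[block(i), block(j), drop = FALSE])) /
        sqrt(within_tr[i] * within_tr[j])
    } else {
      v <- stats::cor(as.vector(R[, block(i)]), as.vector(R[, block(j)]))
    }
    out[i, j] <- out[j, i] <- v
  }
  trait_matrix(out, kind = "correlation", labels = paste0("lm", seq_len(L)))
}
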