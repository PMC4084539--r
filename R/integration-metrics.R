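#' Relative eigenvalue standard deviation (eigenvalue dispersion)
#'
#' Standard deviation of the eigenvalues of a trait matrix scaled to its
#' theoretical maximum given the trace and dimension, so that 0 means no
#' integration (all eigenvalues equal) and 1 means total integration (all
#' variance on one axis). For an N-trait correlation matrix the maximum
#' eigenvalue variance is N - 1, and for an equicorrelation matrix with
#' common correlation r the index equals |r| exactly; in general, for any
#' true correlation matrix, its square equals the mean squared off-diagonal
#' correlation.
#'
#' @param M a symmetric PSD `trait_matrix` (bend first otherwise).
#' @return a number in `[0, 1]`.
#' @export
rel_eigen_sd <- function(M) {
  check_square_symmetric(M, tol = 1e-8)
  N <- nrow(M)
  if (N < 2) stop("need at least 2 traits", call. = FALSE)
  lam <- eigen(unclass(M), symmetric = TRUE, only.values = TRUE)$values
  tr <- sum(lam)
  if (tr <= 0) stop("matrix has non-positive trace", call. = FALSE)
  v <- mean((lam - tr / N)^2)                 # population variance
  v_max <- tr^2 * (N - 1) / N^2               # all variance on one axis
  sqrt(v / v_max)
}

#' Mean squared off-diagonal correlation
#'
#' The classic whole-matrix integration index: the mean of the squared
#' correlations over all unordered trait pairs. Covariance inputs are
#' standardized to correlation first.
#'
#' @param M a `trait_matrix`.
#' @return a number in `[0, 1]`.
#' @export
mean_squared_correlation <- function(M) {
  N <- nrow(M)
  if (N < 2) stop("need at least 2 traits", call. = FALSE)
  R <- unclass(as_correlation(M))
  mean(R[upper.tri(R)]^2)
}

# --- module partitions -------------------------------------------------------

#' Module partitions
#'
#' A `module_partition` maps trait (or landmark) ids to module ids. For
#' landmark-level partitions applied to coordinate-level data, all D
#' coordinates of a landmark share the landmark's module.
#'
#' @param assignment named character vector: names are trait/landmark ids,
#'   values are module ids.
#' @return a `module_partition` object.
#' @export
module_partition <- function(assignment) {
  stopifnot(!is.null(names(assignment)), !anyDuplicated(names(assignment)))
  if (length(unique(assignment)) < 2) {
    stop("a partition needs at least 2 modules", call. = FALSE)
  }
  structure(as.character(stats::setNames(as.character(assignment),
                                         names(assignment))),
            names = names(assignment), class = "module_partition")
}

#' Read a module partition from a YAML file
#'
#' The file maps module name to a list of landmark/trait ids, e.g. the
#' shipped six-module carnivoran cranial partition
#' (`system.file("extdata", "six_module.yaml", package = "modmacro")`).
#'
#' @param path YAML file path.
#' @return a `module_partition`.
#' @export
read_partition_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  ids <- unlist(y, use.names = FALSE)
  mods <- rep(names(y), lengths(y))
  module_partition(stats::setNames(mods, ids))
}

#' Expand a landmark-level partition to coordinate-level trait labels
#'
#' @param partition a `module_partition` over landmark ids (`lm<i>`).
#' @param n_dim 2 or 3.
#' @return a `module_partition` over `lm<i>_<axis>` labels.
#' @export
expand_partition <- function(partition, n_dim) {
  axes <- c("x", "y", "z")[seq_len(n_dim)]
  ids <- as.vector(t(outer(names(partition), axes, paste, sep = "_")))
  module_partition(stats::setNames(rep(unclass(partition), each = n_dim), ids))
}

# turn (data | covariance matrix, partition) into a covariance matrix plus
# block index list, ordered by module
partition_blocks <- function(C, partition) {
  labs <- rownames(C)
  miss <- setdiff(names(partition), labs)
  if (length(miss)) {
    stop("partition names absent from data: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  mods <- unique(unclass(partition))
  lapply(stats::setNames(mods, mods), function(m) {
    match(names(partition)[unclass(partition) == m], labs)
  })
}

data_covariance <- function(data) {
  if (inherits(data, "aligned_shapes")) {
    flat <- residual_matrix(data, "species-mean")
    C <- stats::cov(flat)
    trait_matrix(C, kind = "covariance", labels = colnames(flat))
  } else if (inherits(data, "trait_matrix")) {
    data
  } else if (is.matrix(data)) {
    trait_matrix(stats::cov(data), kind = "covariance",
                 labels = colnames(data) %||% paste0("t", seq_len(ncol(data))))
  } else stop("data must be aligned_shapes, trait_matrix, or a data matrix",
              call. = FALSE)
}

rv_pair <- function(C, i, j) {
  C11 <- C[i, i, drop = FALSE]; C22 <- C[j, j, drop = FALSE]
  C12 <- C[i, j, drop = FALSE]
  den <- sqrt(sum(C11 * C11) * sum(C22 * C22))
  if (den <= 0) stop("zero-variance block in RV computation", call. = FALSE)
  sum(C12 * C12) / den   # tr(C12 C21) = ||C12||_F^2 ; tr(C11^2) = ||C11||_F^2
}

#' RV coefficient for a modular hypothesis
#'
#' For two blocks, `RV = tr(C12 C21) / sqrt(tr(C11^2) tr(C22^2))`; for more
#' than two modules, the unweighted mean of all pairwise RVs (the convention
#' of the confirmatory-modularity software this mirrors; the minimum pairwise
#' RV is available via `summary = "min"`). Lower RV means stronger
#' modularity.
#'
#' @param data an `aligned_shapes` object, a covariance/correlation
#'   `trait_matrix`, or a specimen x trait data matrix.
#' @param partition a `module_partition` over the trait labels (use
#'   [expand_partition()] for landmark-level partitions on coordinate data).
#' @param summary `"mean"` (default) or `"min"` over module pairs.
#' @return RV coefficient in `[0, 1]`.
#' @export
rv_coefficient <- function(data, partition, summary = c("mean", "min")) {
  summary <- match.arg(summary)
  C <- unclass(data_covariance(data))
  blocks <- partition_blocks(C, partition)
  if (length(blocks) < 2) stop("need at least 2 modules", call. = FALSE)
  if (any(lengths(blocks) < 2)) {
    stop("every module needs at least 2 scalar traits", call. = FALSE)
  }
  pairs <- utils::combn(length(blocks), 2)
  rvs <- apply(pairs, 2, function(p) rv_pair(C, blocks[[p[1]]], blocks[[p[2]]]))
  if (summary == "mean") mean(rvs) else min(rvs)
}

#' Permutation test of a modular hypothesis via the RV coefficient
#'
#' Compares the observed RV to RVs of random reassignments of landmarks to
#' modules with the same module sizes. Permutation operates on whole
#' landmarks: all D coordinates of a landmark move together. The p-value is
#' the add-one proportion of permuted RVs less than or equal to the observed
#' one (one-sided in the modularity direction, so small p supports the
#' hypothesized modules).
#'
#' @param data as in [rv_coefficient()].
#' @param partition a `module_partition`; for coordinate-level data pass a
#'   landmark-level partition together with `n_dim`, or an already expanded
#'   coordinate partition with `landmark_of` giving the permutation units.
#' @param n_perm number of random partitions (values below 100 give a very
#'   coarse p and trigger a warning).
#' @param seed integer seed.
#' @param n_dim dimensionality used to expand a landmark-level partition.
#' @param landmark_of optional named vector mapping trait label to permutation
#'   unit; defaults to the `lm<i>` prefix for `lm<i>_<axis>` labels, else each
#'   trait is its own unit.
#' @param summary passed to [rv_coefficient()].
#' @return list with `rv`, `p`, `n_perm`, `perm_rv` (the null sample).
#' @export
rv_permutation_test <- function(data, partition, n_perm = 10000L, seed = 1L,
                                n_dim = NULL, landmark_of = NULL,
                                summary = "mean") {
  if (n_perm < 100) warning("n_perm < 100: p-value resolution is very coarse")
  if (!is.null(n_dim)) partition <- expand_partition(partition, n_dim)
  C <- data_covariance(data)
  labs <- rownames(C)
  if (is.null(landmark_of)) {
    landmark_of <- if (all(grepl("^lm[0-9]+_[xyz]$", names(partition)))) {
      stats::setNames(sub("_[xyz]$", "", names(partition)), names(partition))
    } else {
      stats::setNames(names(partition), names(partition))
    }
  }
  units <- unique(unname(landmark_of[names(partition)]))
  unit_module <- vapply(units, function(u) {
    unique(unclass(partition)[landmark_of[names(partition)] == u])
  }, character(1))
  obs <- rv_coefficient(C, partition, summary = summary)
  perm_rv <- with_seed(substream_seed(seed, "rv_permutation_test"), {
    vapply(seq_len(n_perm), function(b) {
      shuffled <- sample(unit_module)
      new_assign <- stats::setNames(
        shuffled[match(landmark_of[names(partition)], units)],
        names(partition))
      rv_coefficient(C, module_partition(new_assign), summary = summary)
    }, numeric(1))
  })
  p <- (1 + sum(perm_rv <= obs)) / (n_perm + 1)
  list(rv = obs, p = p, n_perm = n_perm, perm_rv = perm_rv)
}
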