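#' Trait labels for landmark coordinates
#'
#' Coordinate-level trait labels of the form `lm<i>_<axis>`, the naming used
#' throughout for flattened landmark configurations (row-major by landmark).
#'
#' @param n_landmarks number of landmarks.
#' @param n_dim 2 or 3.
#' @return character vector of length `n_landmarks * n_dim`.
#' @export
landmark_labels <- function(n_landmarks, n_dim) {
  stopifnot(n_dim %in% c(2L, 3L))
  axes <- c("x", "y", "z")[seq_len(n_dim)]
  as.vector(t(outer(seq_len(n_landmarks), axes,
                    function(i, a) paste0("lm", i, "_", a))))
}

#' Draw multivariate-Gaussian specimens
#'
#' Independent draws from N(mean, Sigma), one specimen per row, returned as a
#' specimen table (`specimen`, `species`, then one column per trait). The
#' draw is bit-for-bit reproducible under a fixed seed.
#'
#' @param Sigma a positive-definite `trait_matrix` (bend first if needed).
#' @param mean_shape numeric vector of trait means (recycled scalar allowed).
#' @param n_specimens number of rows (>= 2; a single specimen leaves all
#'   downstream covariances undefined and triggers a warning).
#' @param species_label species name stored in the `species` column.
#' @param seed integer seed.
#' @return data.frame with columns `specimen`, `species`, and the traits.
#' @export
sample_specimens <- function(Sigma, mean_shape = 0, n_specimens,
                             species_label = "sp1", seed = 1L) {
  n <- nrow(Sigma)
  mean_shape <- rep_len(mean_shape, n)
  if (n_specimens < 2) {
    warning("fewer than 2 specimens: downstream covariances are undefined")
  }
  L <- tryCatch(chol(unclass(Sigma)), error = function(e) {
    stop("Sigma is not positive definite; bend_positive_definite() it first",
         call. = FALSE)
  })
  X <- with_seed(substream_seed(seed, paste0("sample_specimens:", species_label)), {
    matrix(stats::rnorm(n_specimens * n), n_specimens, n) %*% L
  })
  X <- sweep(X, 2, mean_shape, "+")
  colnames(X) <- rownames(Sigma)
  data.frame(specimen = paste0(species_label, "_", seq_len(n_specimens)),
             species = species_label, X, check.names = FALSE)
}

#' Multi-species specimen sample
#'
#' Convenience wrapper drawing `n_specimens` per species around
#' species-specific mean shapes (shared within-species covariance), emulating
#' a pooled multi-species landmark sample.
#'
#' @param Sigma shared within-species covariance (`trait_matrix`).
#' @param species_means matrix (species x traits) of mean shapes; rownames
#'   are the species labels.
#' @param n_specimens specimens per species (scalar or per-species vector).
#' @param seed integer seed.
#' @return stacked specimen table.
#' @export
sample_species_panel <- function(Sigma, species_means, n_specimens, seed = 1L) {
  stopifnot(is.matrix(species_means), !is.null(rownames(species_means)))
  n_specimens <- rep_len(n_specimens, nrow(species_means))
  out <- lapply(seq_len(nrow(species_means)), function(i) {
    sample_specimens(Sigma, species_means[i, ], n_specimens[i],
                     species_label = rownames(species_means)[i],
                     seed = substream_seed(seed, paste0("panel:", i)))
  })
  do.call(rbind, out)
}

#' Random pure-birth tree rescaled to unit depth
#'
#' A Yule (pure-birth) topology with exponential branch lengths, rescaled so
#' every root-to-tip path has length exactly 1. Ultrametric, binary, with
#' tips `t1..tn`.
#'
#' @param n_tips number of tips (>= 2).
#' @param seed integer seed.
#' @return an [ape::phylo] tree.
#' @export
random_tree <- function(n_tips, seed = 1L) {
  if (n_tips < 2) stop("a tree needs at least 2 tips", call. = FALSE)
  tree <- with_seed(substream_seed(seed, "random_tree"),
                    ape::rphylo(n_tips, birth = 1, death = 0))
  depths <- ape::node.depth.edgelength(tree)
  tree$edge.length <- tree$edge.length / max(depths)
  tree$tip.label <- paste0("t", seq_len(n_tips))
  tree
}

#' Convert a specimen table to a landmark array
#'
#' @param tab specimen table with `lm<i>_<axis>` columns.
#' @return list with `coords` (n x L x D array), `species`, `specimen`.
#' @export
specimens_to_array <- function(tab) {
  trait_cols <- grep("^lm[0-9]+_[xyz]$", names(tab), value = TRUE)
  if (length(trait_cols) == 0) stop("no lm<i>_<axis> columns found", call. = FALSE)
  lm <- as.integer(sub("^lm([0-9]+)_.*$", "\\1", trait_cols))
  ax <- sub("^lm[0-9]+_", "", trait_cols)
  L <- max(lm)
  axes <- c("x", "y", "z")[c("x", "y", "z") %in% unique(ax)]
  D <- length(axes)
  n <- nrow(tab)
  coords <- array(NA_real_, c(n, L, D),
                  dimnames = list(tab$specimen, paste0("lm", seq_len(L)), axes))
  for (j in seq_along(trait_cols)) {
    coords[, lm[j], match(ax[j], axes)] <- tab[[trait_cols[j]]]
  }
  if (anyNA(coords)) stop("missing landmark coordinates", call. = FALSE)
  list(coords = coords, species = tab$species, specimen = tab$specimen)
}

#' Flatten a landmark array to a specimen x trait matrix
#' @param coords n x L x D array.
#' @return matrix with `lm<i>_<axis>` columns.
#' @export
flatten_landmarks <- function(coords) {
  n <- dim(coords)[1]; L <- dim(coords)[2]; D <- dim(coords)[3]
  out <- matrix(aperm(coords, c(1, 3, 2)), n, L * D)
  colnames(out) <- landmark_labels(L, D)
  rownames(out) <- dimnames(coords)[[1]]
  out
}
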