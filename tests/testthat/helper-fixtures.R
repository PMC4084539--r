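# small fixtures shared across test files, all built in code

# fully-resolved 4-taxon tree with hand-checkable shared path lengths
tree4 <- function() ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")

# star phylogeny: no shared internal branches, V proportional to identity
star_tree <- function(n = 8) {
  tr <- ape::stree(n, type = "star")
  tr$edge.length <- rep(1, nrow(tr$edge))
  tr
}

# wrap a coords array (+ species) as aligned_shapes for formula-level tests
fake_aligned <- function(coords, species = NULL) {
  n <- dim(coords)[1]
  structure(list(coords = coords,
                 species = species %||% rep("sp1", n),
                 specimen = paste0("s", seq_len(n)),
                 centroid_size = rep(1, n),
                 consensus = apply(coords, c(2, 3), mean),
                 iterations = 0L),
            class = "aligned_shapes")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random PD covariance matrix with labels
random_pd_matrix <- function(n, seed) {
  set.seed(seed)
  A <- matrix(rnorm(n * n), n, n)
  trait_matrix(crossprod(A) / n + diag(0.1, n), kind = "covariance")
}

# random correlation matrix (standardized Wishart-style draw)
random_corr_matrix <- function(n, seed) {
  set.seed(seed)
  A <- matrix(rnorm(n * (n + 2)), n + 2, n)
  trait_matrix(stats::cov2cor(crossprod(A)), kind = "correlation")
}
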