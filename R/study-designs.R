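#' Synthetic panel of correlation matrices spanning a range of integration
#'
#' Builds a panel of correlation matrices whose mean squared correlations are
#' evenly spaced over `r2_range`, cycling through three structures: plain
#' equicorrelation, two equal blocks with zero between-block correlation, and
#' five equal blocks with between-block correlation one third of the
#' within-block value. Each structure's within-block correlation is solved in
#' closed form so the matrix hits its integration target exactly, giving a
#' surrogate for a panel of species correlation matrices with a controlled
#' span of integration.
#'
#' @param n_matrices number of matrices (default 97, the classic panel size).
#' @param n_traits traits per matrix (default 50; must allow 2- and 5-block
#'   splits, i.e. be divisible by 10).
#' @param r2_range range of mean squared correlation to span (default the
#'   observed 0.06-0.23).
#' @param seed integer seed: shuffles which structure lands on which target
#'   so structure and integration level are not confounded.
#' @return named list of correlation `trait_matrix` objects in increasing
#'   order of target integration.
#' @export
correlation_matrix_panel <- function(n_matrices = 97, n_traits = 50,
                                     r2_range = c(0.06, 0.23), seed = 1L) {
  stopifnot(n_matrices >= 3, n_traits %% 10 == 0)
  targets <- seq(r2_range[1], r2_range[2], length.out = n_matrices)
  n_pairs <- n_traits * (n_traits - 1) / 2
  pairs_within <- function(sizes) sum(sizes * (sizes - 1) / 2)
  structures <- with_seed(substream_seed(seed, "correlation_matrix_panel"), {
    sample(rep_len(c("equi", "block2", "block5"), n_matrices))
  })
  build <- function(kind, m) {
    switch(kind,
      equi = uniform_correlation_matrix(n_traits, sqrt(m)),
      block2 = {
        sizes <- rep(n_traits / 2, 2)
        rho_w <- sqrt(m * n_pairs / pairs_within(sizes))
        block_correlation_matrix(sizes, rho_w, 0)
      },
      block5 = {
        sizes <- rep(n_traits / 5, 5)
        pw <- pairs_within(sizes); pb <- n_pairs - pw
        # rho_b = rho_w / 3: m = (pw + pb/9) rho_w^2 / n_pairs
        rho_w <- sqrt(m * n_pairs / (pw + pb / 9))
        block_correlation_matrix(sizes, rho_w, rho_w / 3)
      })
  }
  out <- lapply(seq_len(n_matrices), function(i) build(structures[i], targets[i]))
  names(out) <- sprintf("m%02d_%s", seq_len(n_matrices), structures)
  out
}
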