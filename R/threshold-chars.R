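#' Threshold-model simulation of correlated discrete characters
#'
#' Evolves k binary characters along a tree via latent continuous
#' liabilities. Each character's liability starts at 0 at the root; on every
#' branch a vector of correlated Gaussian changes `r* = G %*% r` is added
#' (with `G` the Cholesky factor of the character correlation matrix and `r`
#' standard normal), scaled by the square root of the branch length under
#' the anagenetic model or applied once per branch regardless of length
#' under the punctuational model. A character's state toggles when the
#' liability accumulated since its last toggle reaches the threshold in
#' magnitude (crossing `m` thresholds in one branch flips the state `m`
#' times, i.e. the state changes if `m` is odd), after which the accumulator
#' resets. A classic sign-of-liability variant (`criterion = "sign"`: state
#' is 1 wherever the raw accumulated liability is positive) is available.
#'
#' @param tree an [ape::phylo] tree (>= 4 tips).
#' @param block_corr k x k correlation `trait_matrix` with a module/block
#'   partition (see [block_correlation_matrix()]); bent if singular.
#' @param threshold positive threshold on accumulated liability. The default
#'   0.5 on a unit-depth tree (where root-to-tip liability standard
#'   deviation is 1) yields characters with a few state changes per path.
#' @param model `"anagenetic"` or `"punctuational"`.
#' @param seed integer seed.
#' @param criterion `"toggle"` (accumulate-and-reset, default) or `"sign"`.
#' @return a `character_matrix`: taxa x characters 0/1 matrix with
#'   attributes `blocks` (character -> block id), `model`, `threshold`,
#'   `seed`.
#' @export
simulate_characters <- function(tree, block_corr, threshold = 0.5,
                                model = c("anagenetic", "punctuational"),
                                seed = 1L, criterion = c("toggle", "sign")) {
  model <- match.arg(model)
  criterion <- match.arg(criterion)
  if (threshold <= 0) stop("threshold must be positive", call. = FALSE)
  ntip <- length(tree$tip.label)
  if (ntip < 4) stop("need at least 4 tips", call. = FALSE)
  M <- bend_positive_definite(block_corr)
  k <- nrow(M)
  Lc <- t(chol(unclass(M)))
  edge <- tree$edge
  # topology-only traversal order: punctuational results must not depend
  # on branch lengths, including through the RNG stream
  ord <- ape::reorder.phylo(tree, "cladewise", index.only = TRUE)
  nnode <- ntip + tree$Nnode
  res <- with_seed(substream_seed(seed, "simulate_characters"), {
    acc <- matrix(0, nnode, k)      # liability since last toggle (or raw, for sign)
    state <- matrix(0L, nnode, k)
    for (e in ord) {
      pa <- edge[e, 1]; ch <- edge[e, 2]
      scale <- if (model == "anagenetic") sqrt(tree$edge.length[e]) else 1
      inc <- scale * drop(Lc %*% stats::rnorm(k))
      a <- acc[pa, ] + inc
      s <- state[pa, ]
      if (criterion == "toggle") {
        m <- floor(abs(a) / threshold)
        toggled <- m > 0
        s <- (s + m %% 2L) %% 2L
        a[toggled] <- 0
      } else {
        s <- as.integer(a > 0)
      }
      acc[ch, ] <- a
      state[ch, ] <- s
    }
    state[seq_len(ntip), , drop = FALSE]
  })
  dimnames(res) <- list(tree$tip.label, paste0("c", seq_len(k)))
  blocks <- tm_partition(M)
  if (!is.null(blocks)) names(blocks) <- colnames(res)
  structure(res, blocks = blocks, model = model, threshold = threshold,
            seed = seed, class = c("character_matrix", "matrix", "array"))
}

#' Pairwise character distances (polarity-free mismatch)
#'
#' For characters i and j, `m` is the fraction of taxa at which the two
#' state columns disagree and the distance is `min(m, 1 - m)`, so a
#' character and its complement are at distance 0 (state labels are
#' arbitrary). A pair of invariant characters sits at distance 0 and
#' triggers a warning.
#'
#' @param chars taxa x characters 0/1 matrix.
#' @return k x k symmetric distance matrix with zero diagonal.
#' @export
character_distances <- function(chars) {
  X <- unclass(chars)
  if (ncol(X) < 2 || nrow(X) < 2) stop("need >= 2 characters and >= 2 taxa",
                                       call. = FALSE)
  if (!all(X %in% c(0, 1))) stop("states must be 0/1", call. = FALSE)
  n <- nrow(X)
  agree <- (crossprod(X) + crossprod(1 - X)) / n
  m <- 1 - agree
  d <- pmin(m, 1 - m)
  diag(d) <- 0
  const <- apply(X, 2, function(v) length(unique(v)) == 1)
  if (sum(const) >= 2) {
    warning("invariant character pairs are at distance 0: ",
            paste(colnames(X)[const], collapse = ", "))
  }
  d
}

#' Principal coordinates analysis of a distance matrix
#'
#' Classical metric scaling (double centering of squared distances followed
#' by eigendecomposition); axes with non-positive eigenvalues are dropped
#' and their count reported. When all eigenvalues are non-negative the
#' pairwise Euclidean distances in the embedding reproduce the input
#' distances exactly.
#'
#' @param dist symmetric distance matrix (or `dist` object) with zero
#'   diagonal.
#' @return list with `coordinates` (items x axes), `eigenvalues`
#'   (non-increasing, positive only), `n_dropped` (non-positive axes).
#' @export
pco_embed <- function(dist) {
  D <- as.matrix(dist)
  if (nrow(D) != ncol(D) || max(abs(D - t(D))) > 1e-8) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  n <- nrow(D)
  B <- -0.5 * scale(t(scale(t(D^2), scale = FALSE)), scale = FALSE)
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  tol <- 1e-10 * max(abs(e$values), 1e-300)
  keep <- which(e$values > tol)
  coords <- if (length(keep)) {
    sweep(e$vectors[, keep, drop = FALSE], 2, sqrt(e$values[keep]), "*")
  } else matrix(0, n, 0)
  rownames(coords) <- rownames(D)
  list(coordinates = coords, eigenvalues = e$values[keep],
       n_dropped = n - length(keep))
}

#' Within- versus between-block distance comparison
#'
#' One-sided test that pairwise distances among characters of the same block
#' are smaller than distances between characters of different blocks, either
#' on the raw character distances or in the PCO embedding (`space = "pco"`).
#' The statistic is the Mann-Whitney U of within- versus between-block
#' pairs; because pairwise distances sharing a character are dependent, the
#' usual rank-sum reference distribution is anticonservative, so the p-value
#' is computed by permuting block labels over characters (which is exact
#' under the null of exchangeable characters), with the add-one rule.
#'
#' @param chars a `character_matrix` (or a distance matrix plus `blocks`).
#' @param blocks optional character -> block map (defaults to the matrix's
#'   `blocks` attribute).
#' @param space `"pco"` (Euclidean distances in the embedding, default) or
#'   `"raw"`.
#' @param n_perm number of block-label permutations.
#' @param seed integer seed for the permutations.
#' @return list with `mean_within`, `mean_between`, `U`, `p`.
#' @export
correlated_pair_distance_test <- function(chars, blocks = NULL,
                                          space = c("pco", "raw"),
                                          n_perm = 999L, seed = 1L) {
  space <- match.arg(space)
  if (inherits(chars, "character_matrix")) {
    blocks <- blocks %||% attr(chars, "blocks")
    d <- suppressWarnings(character_distances(chars))
  } else {
    d <- as.matrix(chars)
  }
  if (is.null(blocks)) stop("block membership required", call. = FALSE)
  if (space == "pco") {
    emb <- pco_embed(d)
    d <- as.matrix(stats::dist(emb$coordinates))
  }
  k <- nrow(d)
  bl <- unname(blocks[colnames(d) %||% names(blocks)])
  ut <- upper.tri(d)
  u_stat <- function(lab) {
    same <- outer(lab, lab, "==")
    w <- d[ut & same]; b <- d[ut & !same]
    # U = number of (within, between) pairs with within < between (+ ties/2)
    r <- rank(c(w, b))
    sum(r[seq_along(w)]) - length(w) * (length(w) + 1) / 2
  }
  same <- outer(bl, bl, "==")
  within <- d[ut & same]
  between <- d[ut & !same]
  if (length(within) < 3 || length(between) < 3) {
    stop("need at least 3 pairs in each group", call. = FALSE)
  }
  obs <- u_stat(bl)
  perm <- with_seed(substream_seed(seed, "pair_distance_test"), {
    vapply(seq_len(n_perm), function(i) u_stat(sample(bl)), numeric(1))
  })
  p <- (1 + sum(perm <= obs)) / (n_perm + 1)   # small U = within smaller
  list(mean_within = mean(within), mean_between = mean(between),
       U = obs, p = p)
}
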