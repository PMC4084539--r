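make_config <- function(seed, L = 6, D = 2) {
  set.seed(seed)
  matrix(rnorm(L * D), L, D)
}

test_that("GPA removes similarity transforms", {
  A <- make_config(1)
  coords <- array(0, c(2, 6, 2))
  coords[1, , ] <- A
  coords[2, , ] <- A
  al <- gpa_align(coords)
  expect_lt(procrustes_distance(al$coords[1, , ], al$coords[2, , ]), 1e-10)

  th <- pi / 6
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  coords[2, , ] <- 2 * (A %*% R) + matrix(c(3, -1), 6, 2, byrow = TRUE)
  al <- gpa_align(coords)
  expect_lt(procrustes_distance(al$coords[1, , ], al$coords[2, , ]), 1e-8)
})

test_that("aligned configurations satisfy the Procrustes invariants", {
  set.seed(42)
  coords <- array(rnorm(8 * 5 * 2, sd = 1), c(8, 5, 2))
  al <- gpa_align(coords)
  for (i in 1:8) {
    conf <- al$coords[i, , ]
    expect_lt(max(abs(colMeans(conf))), 1e-10)          # centered
    expect_equal(sqrt(sum(conf^2)), 1, tolerance = 1e-10) # unit centroid size
  }
  expect_equal(al$consensus, apply(al$coords, c(2, 3), mean), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("two-specimen alignment attains the grid-search rotation minimum", {
  A <- matrix(c(0, 0, 2, 0, 1, 2), 3, 2, byrow = TRUE)
  B <- matrix(c(0, 0, 1.5, 0.2, 0.3, 1.1), 3, 2, byrow = TRUE)
  unitize <- function(m) {
    m <- sweep(m, 2, colMeans(m))
    m / sqrt(sum(m^2))
  }
  A <- unitize(A); B <- unitize(B)
  # brute-force oracle over rotations in 0.001-radian steps
  thetas <- seq(0, 2 * pi, by = 0.001)
  oracle <- min(vapply(thetas, function(th) {
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    sqrt(sum((A %*% R - B)^2))
  }, numeric(1)))
  coords <- array(0, c(2, 3, 2))
  coords[1, , ] <- A; coords[2, , ] <- B
  al <- gpa_align(coords)
  got <- procrustes_distance(al$coords[1, , ], al$coords[2, , ])
  expect_equal(got, oracle, tolerance = 1e-3)
  expect_lte(got, oracle + 1e-6)  # never worse than the grid optimum
})

test_that("GPA output does not depend on specimen order", {
  set.seed(9)
  coords <- array(rnorm(10 * 6 * 2), c(10, 6, 2),
                  dimnames = list(paste0("s", 1:10), NULL, NULL))
  al1 <- gpa_align(coords)
  perm <- c(7, 3, 10, 1, 5, 9, 2, 8, 6, 4)
  al2 <- gpa_align(coords[perm, , ])
  expect_equal(al1$coords[perm, , ], al2$coords, tolerance = 1e-6)
})

test_that("GPA rejects degenerate configurations", {
  coords <- array(1, c(3, 4, 2))  # all landmarks coincide
  expect_error(gpa_align(coords), "degenerate")
})

test_that("pooled within-species covariance pools by degrees of freedom", {
  set.seed(5)
  X <- matrix(rnorm(20 * 4), 20, 4, dimnames = list(NULL, paste0("t", 1:4)))
  single <- pooled_within_species_cov(X, species = rep("a", 20))
  expect_equal(unclass(single), cov(X), ignore_attr = TRUE, tolerance = 1e-12)

  # two groups of 3, two traits: pooled = (2*S1 + 2*S2) / 4, by hand
  Y <- matrix(c(0, 0, 1, 2, 2, 1,   4, 1, 5, 3, 6, 2), 6, 2, byrow = TRUE)
  colnames(Y) <- c("t1", "t2")
  sp <- rep(c("g1", "g2"), each = 3)
  S1 <- cov(Y[1:3, ]); S2 <- cov(Y[4:6, ])
  got <- pooled_within_species_cov(Y, species = sp)
  expect_equal(unclass(got), (2 * S1 + 2 * S2) / 4, ignore_attr = TRUE,
               tolerance = 1e-12)

  expect_warning(pooled_within_species_cov(rbind(Y, Y[1, , drop = FALSE]),
                                           species = c(sp, "lonely")),
                 "lonely")
})

test_that("pooled covariance recovers the generating matrix at large n", {
  Sigma <- uniform_correlation_matrix(4, 0.4)
  means <- matrix(rnorm(3 * 4, sd = 3), 3, 4,
                  dimnames = list(paste0("sp", 1:3), NULL))
  tab <- sample_species_panel(Sigma, means, 1700, seed = 21)
  got <- pooled_within_species_cov(as.matrix(tab[, -(1:2)]), species = tab$species)
  expect_lt(max(abs(unclass(got) - unclass(Sigma))), 0.05)
})

test_that("congruence correlations follow the trace convention", {
  # lm2 deviations identical to lm1 -> entry 1; lm3 independent
  set.seed(13)
  n <- 5000
  base <- matrix(rnorm(n * 2), n, 2)
  coords <- array(0, c(n, 3, 2))
  coords[, 1, ] <- base
  coords[, 2, ] <- base + 5       # same deviations, different location
  coords[, 3, ] <- matrix(rnorm(n * 2), n, 2)
  al <- fake_aligned(coords)
  M <- congruence_correlation_matrix(al, residual_from = "grand-mean")
  expect_equal(diag(unclass(M)), rep(1, 3), ignore_attr = TRUE)
  expect_equal(unclass(M)[1, 2], 1, tolerance = 1e-12)
  expect_lt(abs(unclass(M)[1, 3]), 0.05)

  # zero-variance landmark is an error naming the landmark
  coords[, 3, ] <- 0
  expect_error(congruence_correlation_matrix(fake_aligned(coords)), "lm3")
})

test_that("bending floors eigenvalues without touching eigenvectors", {
  M <- random_pd_matrix(5, seed = 2)
  expect_lt(max(abs(unclass(bend_positive_definite(M)) - unclass(M))), 1e-12)

  # singular 3x3: one zero eigenvalue raised to the floor
  S <- trait_matrix(tcrossprod(matrix(c(1, 1, 0, 0, 1, 1), 3, 2)), "covariance")
  ev <- eigen(unclass(S), only.values = TRUE)$values
  expect_lt(min(ev), 1e-12)
  bent <- bend_positive_definite(S, floor_frac = 1e-8)
  ev2 <- eigen(unclass(bent), only.values = TRUE)$values
  expect_gte(min(ev2), 1e-8 * max(ev) - 1e-14)  # floor, up to recomposition error
  # no eigenvalue decreased, eigenvectors preserved
  expect_true(all(ev2 >= ev - 1e-12))
  v1 <- eigen(unclass(bent), symmetric = TRUE)$vectors[, 1]
  v2 <- eigen(unclass(S), symmetric = TRUE)$vectors[, 1]
  expect_gt(abs(sum(v1 * v2)), 1 - 1e-8)   # same leading axis up to sign

  # rank-1 correlation matrix of 4 traits: recipe checked by explicit eigen
  s <- c(1, -1, 1, 1)
  R1 <- trait_matrix(tcrossprod(s), kind = "correlation")
  bentR <- bend_positive_definite(R1, floor_frac = 1e-8)
  e <- eigen(tcrossprod(s), symmetric = TRUE)
  lam <- pmax(e$values, 1e-8 * max(e$values))
  manual <- stats::cov2cor(e$vectors %*% diag(lam) %*% t(e$vectors))
  expect_equal(unclass(bentR), manual, ignore_attr = TRUE, tolerance = 1e-10)
  expect_gt(min(eigen(unclass(bentR), only.values = TRUE)$values), 0)
  expect_equal(diag(unclass(bentR)), rep(1, 4), ignore_attr = TRUE)

  expect_error(bend_positive_definite(trait_matrix(matrix(0, 3, 3), "covariance")),
               "no positive eigenvalue")
})
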