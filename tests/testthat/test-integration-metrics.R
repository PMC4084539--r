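test_that("eigenvalue dispersion matches its closed forms", {
  expect_equal(rel_eigen_sd(trait_matrix(diag(7), "correlation")), 0)
  expect_equal(rel_eigen_sd(uniform_correlation_matrix(10, 0.9)), 0.9,
               tolerance = 1e-12)
  # consistently-signed rank-1 correlation matrix: maximal dispersion
  s <- c(1, -1, -1, 1)
  expect_equal(rel_eigen_sd(trait_matrix(tcrossprod(s), "correlation")), 1,
               tolerance = 1e-12)
  expect_error(rel_eigen_sd(trait_matrix(matrix(1, 1, 1), "covariance")),
               "at least 2")
})

test_that("mean squared correlation standardizes and averages pairs", {
  expect_equal(mean_squared_correlation(trait_matrix(diag(5), "correlation")), 0)
  expect_equal(mean_squared_correlation(uniform_correlation_matrix(8, 0.9)), 0.81,
               tolerance = 1e-14)
  # covariance input is standardized first
  D <- diag(c(2, 3, 0.5))
  C <- D %*% unclass(uniform_correlation_matrix(3, 0.4)) %*% D
  expect_equal(mean_squared_correlation(trait_matrix(C, "covariance")), 0.16,
               tolerance = 1e-12)
})

test_that("dispersion squared equals mean squared correlation for any correlation matrix", {
  for (i in 1:60) {
    n <- sample(3:15, 1)
    M <- random_corr_matrix(n, seed = 1000 + i)
    expect_equal(rel_eigen_sd(M)^2, mean_squared_correlation(M),
                 tolerance = 1e-12)
  }
})

test_that("eigenvalue dispersion is invariant to trait permutation", {
  M <- random_corr_matrix(8, seed = 4)
  p <- sample(8)
  Mp <- trait_matrix(unclass(M)[p, p], "correlation")
  expect_equal(rel_eigen_sd(Mp), rel_eigen_sd(M), tolerance = 1e-12)
})

test_that("RV coefficient matches the trace formula and its limiting cases", {
  # hand-computable 2+2-trait dataset of 4 specimens
  X <- matrix(c(1, 2, 0, 1,
                2, 1, 1, 3,
                0, 1, 2, 2,
                3, 0, 1, 0), 4, 4, byrow = TRUE,
              dimnames = list(NULL, paste0("t", 1:4)))
  C <- cov(X)
  C11 <- C[1:2, 1:2]; C22 <- C[3:4, 3:4]; C12 <- C[1:2, 3:4]
  by_hand <- sum(diag(C12 %*% t(C12))) /
    sqrt(sum(diag(C11 %*% C11)) * sum(diag(C22 %*% C22)))
  part <- module_partition(setNames(rep(c("a", "b"), each = 2), paste0("t", 1:4)))
  expect_equal(rv_coefficient(X, part), by_hand, tolerance = 1e-12)

  # duplicated block: RV = 1
  X2 <- cbind(X[, 1:2], X[, 1:2])
  colnames(X2) <- paste0("t", 1:4)
  expect_equal(rv_coefficient(X2, part), 1, tolerance = 1e-12)

  # independent blocks at large n: RV near 0
  set.seed(77)
  Z <- matrix(rnorm(5000 * 6), 5000, 6, dimnames = list(NULL, paste0("t", 1:6)))
  part6 <- module_partition(setNames(rep(c("a", "b"), each = 3), paste0("t", 1:6)))
  expect_lt(rv_coefficient(Z, part6), 0.05)
})

test_that("RV is invariant to orthogonal rotation within a block", {
  set.seed(8)
  X <- matrix(rnorm(200 * 6), 200, 6, dimnames = list(NULL, paste0("t", 1:6)))
  X[, 4:6] <- X[, 4:6] + 0.5 * X[, 1:3]
  part <- module_partition(setNames(rep(c("a", "b"), each = 3), paste0("t", 1:6)))
  rv0 <- rv_coefficient(X, part)
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  Xr <- X
  Xr[, 1:3] <- X[, 1:3] %*% Q
  expect_equal(rv_coefficient(Xr, part), rv0, tolerance = 1e-10)
  # and to block ordering
  part_swapped <- module_partition(setNames(rep(c("b", "a"), each = 3),
                                            paste0("t", 1:6)))
  expect_equal(rv_coefficient(X, part_swapped), rv0, tolerance = 1e-14)
})

test_that("multi-module RV averages the pairwise coefficients", {
  set.seed(3)
  X <- matrix(rnorm(300 * 6), 300, 6, dimnames = list(NULL, paste0("t", 1:6)))
  part3 <- module_partition(setNames(rep(c("a", "b", "c"), each = 2),
                                     paste0("t", 1:6)))
  pairwise <- c(
    rv_coefficient(X[, 1:4], module_partition(setNames(rep(c("a", "b"), each = 2),
                                                       paste0("t", 1:4)))),
    rv_coefficient(X[, c(1, 2, 5, 6)],
                   module_partition(setNames(rep(c("a", "c"), each = 2),
                                             paste0("t", c(1, 2, 5, 6))))),
    rv_coefficient(X[, 3:6], module_partition(setNames(rep(c("b", "c"), each = 2),
                                                       paste0("t", 3:6)))))
  expect_equal(rv_coefficient(X, part3), mean(pairwise), tolerance = 1e-12)
  expect_equal(rv_coefficient(X, part3, summary = "min"), min(pairwise),
               tolerance = 1e-12)
})

test_that("RV permutation test detects planted two-module structure", {
  Sigma <- block_correlation_matrix(c(10, 10), 0.7, 0.1)
  tab <- sample_specimens(Sigma, 0, 100, "sp", seed = 31)
  X <- as.matrix(tab[, -(1:2)])
  part <- module_partition(setNames(attr(Sigma, "partition"), colnames(X)))
  res <- rv_permutation_test(X, part, n_perm = 499, seed = 9)
  expect_lt(res$p, 0.05)
  expect_lt(res$rv, 1)

  # deterministic under a fixed seed
  res2 <- rv_permutation_test(X, part, n_perm = 499, seed = 9)
  expect_identical(res$p, res2$p)
  expect_identical(res$perm_rv, res2$perm_rv)

  expect_warning(rv_permutation_test(X, part, n_perm = 50, seed = 1), "coarse")
})

test_that("landmark-level permutation moves whole landmarks", {
  # coordinate-level data with a landmark partition: x/y of a landmark stay
  # together, so permuted RVs form a restricted, reproducible null set
  Sigma <- block_correlation_matrix(c(8, 8), 0.6, 0.0)
  tab <- sample_specimens(Sigma, 0, 80, "sp", seed = 5)
  X <- as.matrix(tab[, -(1:2)])
  colnames(X) <- landmark_labels(8, 2)
  part_lm <- module_partition(setNames(rep(c("face", "vault"), each = 4),
                                       paste0("lm", 1:8)))
  res <- rv_permutation_test(X, part_lm, n_perm = 199, seed = 2, n_dim = 2)
  expect_true(is.finite(res$rv))
  expect_lt(res$p, 0.05)
})

test_that("partition helpers expand and read configurations", {
  part <- module_partition(c(lm1 = "A", lm2 = "A", lm3 = "B", lm4 = "B"))
  ex <- expand_partition(part, 2)
  expect_equal(names(ex), c("lm1_x", "lm1_y", "lm2_x", "lm2_y",
                            "lm3_x", "lm3_y", "lm4_x", "lm4_y"))
  expect_equal(unname(unclass(ex)), rep(c("A", "B"), each = 4))

  six <- read_partition_yaml(system.file("extdata", "six_module_synthetic.yaml",
                                         package = "modmacro"))
  expect_equal(length(six), 49)
  expect_equal(unname(table(unclass(six))[c("AON", "MOL", "ORB", "ZP", "CV", "BC")]),
               c(10, 8, 7, 8, 6, 10), ignore_attr = TRUE)
  two <- read_partition_yaml(system.file("extdata", "two_module_synthetic.yaml",
                                         package = "modmacro"))
  expect_equal(sort(unique(unclass(two))), c("neurocranial", "orofacial"))
  expect_equal(length(two), 49)
})
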