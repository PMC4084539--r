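test_that("ancestral states minimize the weighted squared-change objective", {
  # two tips, equal branches: root is the midpoint
  tr <- ape::read.tree(text = "(A:1,B:1);")
  expect_equal(unname(ancestral_states(tr, c(A = 0, B = 4))[1, 1]), 2)

  # branch lengths 1 and 3: inverse-length weighting puts the root at 1
  tr2 <- ape::read.tree(text = "(A:1,B:3);")
  expect_equal(unname(ancestral_states(tr2, c(A = 0, B = 4))[1, 1]), 1,
               tolerance = 1e-12)

  # 5-tip tree: numeric brute-force minimizer agrees within 1e-6
  tr5 <- random_tree(5, seed = 3)
  set.seed(4)
  x <- setNames(rnorm(5), tr5$tip.label)
  got <- ancestral_states(tr5, x)[, 1]
  obj <- function(a) {
    st <- c(x[tr5$tip.label], a)
    sum((st[tr5$edge[, 1]] - st[tr5$edge[, 2]])^2 / tr5$edge.length)
  }
  opt <- optim(rep(mean(x), tr5$Nnode), obj, method = "BFGS",
               control = list(reltol = 1e-14))
  expect_equal(unname(got), opt$par, tolerance = 1e-6)
  expect_lte(obj(got), opt$value + 1e-10)
})

test_that("ancestral states agree with the Brownian ML reconstruction", {
  tr <- random_tree(12, seed = 6)
  set.seed(7)
  x <- setNames(rnorm(12), tr$tip.label)
  got <- ancestral_states(tr, x)[, 1]
  fa <- phytools::fastAnc(tr, x)
  expect_equal(unname(got), unname(as.numeric(fa)), tolerance = 1e-6)
})

test_that("branch rates are signed changes per unit branch length", {
  tr <- ape::read.tree(text = "(A:0.5,B:0.5);")
  # identical tip values: every rate is zero
  r0 <- branch_rates(tr, c(A = 2, B = 2))
  expect_equal(r0$trait, c(0, 0))

  # root at midpoint 2, so each branch changes by 0.3 over length 0.5
  r <- branch_rates(tr, c(A = 1.7, B = 2.3))
  expect_equal(sort(r$trait), c(-0.6, 0.6), tolerance = 1e-12)

  # doubling branch lengths halves every rate exactly
  tr2 <- random_tree(8, seed = 8)
  set.seed(9)
  x <- matrix(rnorm(8 * 3), 8, 3, dimnames = list(tr2$tip.label, paste0("t", 1:3)))
  r1 <- branch_rates(tr2, x)
  trd <- tr2; trd$edge.length <- 2 * trd$edge.length
  r2 <- branch_rates(trd, x)
  cols <- paste0("t", 1:3)
  expect_equal(as.matrix(r2[cols]), as.matrix(r1[cols]) / 2, tolerance = 1e-12)
})

test_that("per-landmark rates are non-negative block displacements", {
  tr <- random_tree(6, seed = 10)
  set.seed(11)
  x <- matrix(rnorm(6 * 4), 6, 4,
              dimnames = list(tr$tip.label, landmark_labels(2, 2)))
  r <- branch_rates(tr, x, per_landmark = TRUE)
  expect_equal(setdiff(names(r), c("parent", "child", "branch_length", "terminal")),
               c("lm1", "lm2"))
  expect_true(all(r$lm1 >= 0 & r$lm2 >= 0))
  # consistency with the signed coordinate rates
  rs <- branch_rates(tr, x)
  expect_equal(r$lm1, sqrt(rs$lm1_x^2 + rs$lm1_y^2), tolerance = 1e-12)
})

test_that("rate totals respect branch scope", {
  star <- star_tree(5)
  set.seed(12)
  x <- matrix(rnorm(5 * 2), 5, 2,
              dimnames = list(star$tip.label, c("t1", "t2")))
  r <- branch_rates(star, x)
  tot <- landmark_rate_totals(r)
  expect_equal(tot$total_all, tot$total_terminal)  # star: all branches terminal

  tr <- random_tree(10, seed = 13)
  set.seed(14)
  y <- matrix(rnorm(10 * 2), 10, 2, dimnames = list(tr$tip.label, c("t1", "t2")))
  tot2 <- landmark_rate_totals(branch_rates(tr, y))
  expect_true(all(tot2$total_terminal <= tot2$total_all + 1e-12))
})

test_that("module rate tests report the full battery and degenerate cases", {
  part <- module_partition(setNames(rep(c("A", "B"), each = 4),
                                    paste0("lm", 1:8)))
  totals <- data.frame(landmark = paste0("lm", 1:8),
                       total_all = rep(1, 8), total_terminal = rep(1, 8))
  res <- suppressWarnings(module_rate_tests(totals, part))
  expect_true(all(res$pairwise$p_bonferroni == 1))

  # a rate column against itself has Spearman rho exactly 1
  totals2 <- data.frame(landmark = paste0("lm", 1:8),
                        total_all = c(1, 3, 2, 5, 4, 7, 6, 8),
                        total_terminal = 0)
  v <- setNames(totals2$total_all, totals2$landmark)
  res2 <- suppressWarnings(module_rate_tests(totals2, part, landmark_variances = v))
  expect_equal(res2$spearman_overall$rho, 1)

  # modules below 3 landmarks are excluded with a warning
  part_small <- module_partition(setNames(c("A", "A", "A", "A", "B", "B", "B", "C"),
                                          paste0("lm", 1:8)))
  expect_warning(module_rate_tests(totals2, part_small, landmark_variances = v),
                 "C")
})

test_that("faster modules are detected by the Mann-Whitney comparison", {
  tr <- random_tree(36, seed = 15)
  n_rep <- 200
  hits <- 0
  for (i in seq_len(n_rep)) {
    # module A landmarks evolve with 4x the variance of module B
    scales <- rep(c(2, 1), each = 10)   # sd factors; variance ratio 4
    Sigma <- trait_matrix(diag(rep(scales^2, each = 2)), "covariance",
                          labels = landmark_labels(20, 2))
    tips <- simulate_bm(tr, Sigma, seed = substream_seed(15, paste0("pw:", i)))
    tot <- landmark_rate_totals(branch_rates(tr, tips, per_landmark = TRUE))
    part <- module_partition(setNames(rep(c("A", "B"), each = 10),
                                      paste0("lm", 1:20)))
    res <- module_rate_tests(tot, part)
    a_gt_b <- res$module_means["A"] > res$module_means["B"]
    if (a_gt_b && res$pairwise$p_raw[1] < 0.05) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.90)
})
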