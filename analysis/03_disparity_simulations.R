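#!/usr/bin/env Rscript
# Correlated vs uncorrelated Brownian motion on a tree: disparity effects.
#
# Ten 30-trait equicorrelation matrices spanning eigenvalue dispersion
# 0.19-0.46 are each simulated 1000 times on a 36-tip unit-depth pure-birth
# tree, with trait correlations intact and with covariances zeroed (equal
# variances, so only trait relationships differ between arms). Also traces
# single-lineage divergence fans for the 10-trait var-1 / cov-0.9 complex.

suppressPackageStartupMessages(library(modmacro))
SEED <- 1L
dir.create("results", showWarnings = FALSE)

ladder <- integration_ladder(10, 30, c(0.19, 0.46))
tree36 <- random_tree(36, seed = substream_seed(SEED, "tree36"))
ape::write.tree(tree36, "results/tree36.nwk")

scan <- integration_vs_range_scan(ladder, tree36, n_reps = 1000,
                                  seed = substream_seed(SEED, "scan"))
write.csv(scan$table, "results/disparity_ratios.csv", row.names = FALSE)
print(scan$table, digits = 3)
message(sprintf(
  "range ratio vs eigenvalue dispersion: Spearman rho = %.2f (p = %.3g)",
  scan$spearman$rho, scan$spearman$p))
message("mean-distance ratios sit just below 1; range ratios exceed 1 and grow ",
        "with integration: correlations repartition variance into preferred ",
        "directions and let extreme morphologies evolve.")

# single-lineage divergence fans: 10 traits, variances 1, covariances 0.9 / 0
S <- uniform_correlation_matrix(10, 0.9)
for (arm in c("correlated", "uncorrelated")) {
  M <- if (arm == "correlated") S else decorrelate(S)
  tra <- divergence_trajectories(M, n_steps = 100, n_reps = 1000,
                                 seed = substream_seed(SEED, paste0("traj_", arm)))
  q <- data.frame(step = seq_len(nrow(tra$quantiles)), tra$quantiles,
                  check.names = FALSE)
  write.csv(q, sprintf("results/divergence_quantiles_%s.csv", arm),
            row.names = FALSE)
  message(sprintf(
    "%s arm at step 100: median distance %.1f, 95%% band width %.1f",
    arm, q[100, "50%"], q[100, "97.5%"] - q[100, "2.5%"]))
}
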