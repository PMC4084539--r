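---
title: "Simulating the macroevolutionary consequences of phenotypic integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating the macroevolutionary consequences of phenotypic integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question

Phenotypic integration — statistical covariation among morphological traits
arising from shared genetics, development and function — is ubiquitous in
vertebrate skeletons. Its macroevolutionary consequences are harder to pin
down: does integration change how far, in which directions, and how fast
clades move through morphospace? `modmacro` implements a connected set of
simulation studies around that question, using the mammalian cranium as the
motivating system:

1. confirmatory tests of modular hypotheses on landmark data
   (RV coefficient with landmark-level permutation);
2. random-skewers probing of trait matrices to measure how integration
   shapes the response to selection;
3. correlated versus uncorrelated Brownian motion on phylogenies, comparing
   morphological disparity between the two regimes;
4. per-landmark evolutionary rates compared across cranial modules;
5. a liability-threshold simulation of correlated discrete characters, with
   principal-coordinates diagnostics of character non-independence.

Because no specimen-level dataset ships with the package, a synthetic-data
module generates every input — correlation matrices with controlled
integration and modular structure, multi-species landmark samples, and
pure-birth trees — with known ground truth. That choice governs what the
test suite can and cannot establish (see *What the synthetic data do and do
not show* below).

## Trait matrices and integration indices

The central container is a labelled symmetric trait matrix tagged as
covariance or correlation, optionally carrying a trait-to-module partition.
Two whole-matrix integration indices are provided:

* **Relative eigenvalue standard deviation** (`rel_eigen_sd`): the standard
  deviation of the eigenvalues divided by its theoretical maximum given the
  trace and dimension. 0 means all eigenvalues equal (no integration); 1
  means all variance on a single axis.
* **Mean squared correlation** (`mean_squared_correlation`): the average of
  squared off-diagonal correlations over unordered pairs; covariance inputs
  are standardized first.

For any true correlation matrix of `N` traits the population eigenvalue
variance equals `(N - 1)` times the mean squared correlation, so the square
of the first index equals the second *exactly*. This identity is the
package's primary cross-metric oracle: it is checked to 1e-12 over a
thousand random correlation matrices, and it is why the two indices are
near-perfectly correlated across any panel whose integration varies.

For an equicorrelation matrix (all off-diagonals `r`) the relative
eigenvalue standard deviation equals `|r|` in closed form. The
`integration_ladder` generator exploits this to build matrix sequences whose
integration is *exactly* evenly spaced — the default ladder spans 0.19–0.46,
the span observed across real mammalian cranial datasets. A single-factor
construction with random loadings (bisected onto each target) provides
structural diversity when equicorrelation is too special.

Singular matrices are made usable by **bending** (`bend_positive_definite`):
eigenvalues below `floor_frac` (default 1e-8) times the largest eigenvalue
are raised to that floor and the matrix is recomposed. Eigenvectors are
untouched, no eigenvalue ever decreases, and correlation matrices are
rescaled back to unit diagonal.

## Landmarks, alignment and matrix estimation

`gpa_align` is a standard generalized Procrustes superimposition: centering,
unit-centroid-size scaling, and iterative rotation (reflections forbidden)
to a consensus re-estimated until it moves less than `tol = 1e-10`. Two
conventions are deliberate:

* no tangent-space projection by default — at the within-species scales the
  generator produces (coordinate noise a few percent of centroid size) the
  curvature correction is far below the effects under study; a `project`
  flag exists;
* after convergence the common frame is rotated to the principal axes of
  the consensus with a deterministic sign convention, so the output is
  invariant to specimen ordering.

Two matrix estimators feed downstream stages. `pooled_within_species_cov`
pools deviations from each species' own mean, weighting by within-species
degrees of freedom; species represented by a single specimen are dropped,
not imputed. `congruence_correlation_matrix` gives the landmark-level (L × L)
picture: entry (i, j) is the trace of the cross-covariance block between two
landmarks' coordinates scaled by the geometric mean of their within-landmark
traces. The literature that introduced the congruence coefficient does not
print a single canonical formula for the landmark-coordinate case, so this
trace convention — rotation-sensible and scale-free — is our documented
choice, with a vectorized-Pearson alternative behind `method = "pearson"`.
Skewers and Brownian simulations consume coordinate-level covariance
matrices by default; landmark-level congruence matrices serve the
integration summaries. Both levels are exposed because published analyses
are frequently ambiguous about which one fed which stage.

## Confirmatory modularity: the RV coefficient

For two trait blocks, `RV = tr(C12 C21) / sqrt(tr(C11^2) tr(C22^2))`; for
more than two modules the package reports the unweighted mean of pairwise
RVs (the convention of the widely used confirmatory-modularity software),
with the minimum available behind a flag. Lower RV means stronger
modularity. Significance comes from random reassignments of landmarks to
modules with the same module sizes — whole landmarks move with all their
coordinates, since coordinates of one landmark are trivially correlated.
Permutations are unrestricted (no spatial-contiguity constraint; none is
described for the original analyses) and the p-value uses the add-one rule
counting permuted RVs less than or equal to the observed one. Whether the
original test counted `<` or `<=` is not recorded anywhere we could find;
`<=` is the conservative choice.

The shipped six-module cranial partition (anterior oral–nasal 10,
molar–palate 8, orbit 7, zygomatic–pterygoid 8, vault 6, basicranium 10
landmarks — 49 of 51 landmarks assigned) and the orofacial–neurocranial
two-module grouping use synthetic landmark ids (`lm1..lm49`); real datasets
supply their own YAML mapping.

## Random skewers

A skewer is a uniform random unit selection vector `beta`; the response of a
G-matrix analogue is `z = G beta`. Per skewer the package reports
respondability `||z||`, evolvability `beta'z`, conditional evolvability
`1/(beta' G^-1 beta)`, flexibility `cos(beta, z)`, and constraint — the
absolute cosine between the response and the leading eigenvector of `G`.
The constraint formula is not printed in the study this package follows; the
absolute-cosine convention of the evolvability literature is implemented and
documented as a convention, not asserted as identical to the original. Under
a leading-eigenvalue tie (identity matrices, or block-diagonal matrices with
identical blocks) the leading eigenvector is undefined and constraint is
reported as `NA` rather than a sign-arbitrary number. Conditional
evolvability switches to a pseudo-inverse when the condition number exceeds
1e12.

`skewer_panel_summary` scores a panel of matrices. Its `shared_skewers`
switch matters more than it looks:

* `TRUE` (default): every matrix of a given dimension is probed by the same
  skewer set. Identical matrices give identical rows, and cross-matrix
  contrasts in respondability, flexibility and constraint are free of
  skewer-sampling noise.
* `FALSE`: each matrix gets an independent draw, mirroring a study in which
  every species dataset was probed separately. This is the only honest mode
  for asking whether *evolvability* relates to integration: on correlation
  matrices the spherical expectation of evolvability is `trace/N = 1`
  regardless of integration, so any sample correlation is Monte-Carlo noise.
  With shared skewers that noise is common to all matrices and the
  correlation collapses to exactly ±1; with independent draws it is a null
  correlation whose standard error is about `1/sqrt(n_matrices - 1)`. The
  sign-pattern check therefore runs on a 97-matrix panel (null s.e. ≈ 0.1,
  making the |r| < 0.3 criterion a ~3-sigma statement); at 10 matrices the
  same check would be uninformative (null s.e. ≈ 0.33).

On the synthetic ladder the expected pattern emerges: respondability and
constraint increase with integration, flexibility decreases, evolvability
shows no substantial relationship. The mean evolvability over many skewers
converges to `trace(G)/N` — an analytic expectation used as a simulator
oracle.

## Correlated vs uncorrelated Brownian motion and disparity

`simulate_bm` evolves a multivariate phenotype from a zero root state; each
branch adds `sqrt(t) * L eps` with `L` the Cholesky factor of the trait
matrix. Drawing one exact Gaussian increment per branch is distributionally
identical to a fine-stepped walk along the branch and much faster; the
stepwise walk survives in `divergence_trajectories`, which tracks
single-lineage distance fans per unit-time step. Tips are jointly Gaussian
with covariance (shared path length) ⊗ Sigma — verified against that
Kronecker form by Monte Carlo on four-tip trees.

The paired experiment runs `n_reps` simulations with the matrix as supplied
and `n_reps` with `decorrelate(Sigma)` — same diagonal, zero off-diagonals,
so the trace (expected squared divergence per unit time) is conserved
*exactly*. The two arms use independent draws, as in the original design; a
common-random-numbers mode is deliberately not the default since the
published ratios reflect independent runs. Three disparity statistics are
computed per run: mean pairwise distance, mean distance to the grand mean,
and range (the largest pairwise distance).

The mechanism this machinery demonstrates: trait correlations repartition
variance into preferred directions without changing its total. Mean
dissimilarity statistics are nearly unchanged (in fact slightly *smaller*
with correlations, by Jensen's inequality on the square root), while the
range ratio rises well above 1 and grows with integration — extreme
morphologies become more accessible. On the default ladder (10
equicorrelation matrices spanning 0.19–0.46, 36-tip unit-depth tree, 1000
replicates per arm) the Spearman correlation between range ratio and
integration is 1.0, and mean-distance ratios fall in 0.96–0.995.

Tree conventions: pure-birth topologies rescaled to unit root-to-tip depth,
because the original studies never state their tree calibration; unit depth
makes variance scales comparable across runs and seeds. Default 36 tips for
the disparity experiments and 47 for the character simulations, matching
the motivating carnivoran analyses.

## Per-landmark rates across modules

The original rate analysis used an adaptive-peak "independent evolution"
estimator whose algorithm lives in software we do not reproduce; this
package implements a deliberately simple, fully specified replacement and
declares non-equivalence. `ancestral_states` minimizes the sum over branches
of squared change divided by branch length (weighted squared-change, equal
to the Brownian maximum-likelihood reconstruction with tips fixed; verified
against a brute-force minimizer and against an independent ML
implementation). `branch_rates` divides per-branch changes by branch length
— signed for scalar traits, Euclidean per landmark block — and
`landmark_rate_totals` sums absolute rates over all branches and over
terminal branches only (terminal and internal rates of one lineage are not
independent, hence the separate scope). Rates are exactly equivariant under
branch-length rescaling. "Relative change independent of trait size" is
handled by operating on Procrustes shape coordinates, which are already
size-free; dividing by ancestral values is ill-defined for coordinates that
cross zero.

`module_rate_tests` reproduces the comparison battery: a Shapiro–Wilk gate
(summed rates are right-skewed, justifying rank tests), Spearman rate-vs-
variance correlations overall and per module, Kruskal–Wallis across modules,
all pairwise Mann–Whitney comparisons Bonferroni-corrected over the 15
module pairs, and a pooled strong-vs-weak two-group comparison. Parameter
recovery is the key validation: when landmarks evolve with planted rate
scales on a 36-tip tree, the Spearman correlation between planted scales and
estimated summed rates is above 0.9.

## Threshold-model characters and PCO diagnostics

Binary characters evolve via latent liabilities: per branch, correlated
Gaussian changes `r* = G r` (Cholesky factor times standard normals) are
added — scaled by the square root of branch length under the *anagenetic*
model, once per branch regardless of length under the *punctuational*
model (whose output is therefore exactly invariant to branch lengths,
including through the random-number stream). The published description does
not specify the threshold criterion, so the package implements a
documented toggle dynamic: a character's state flips when the liability
accumulated since its last toggle reaches the threshold in magnitude
(crossing `m` thresholds in one branch flips `m` times), after which the
accumulator resets; a classic sign-of-liability variant is selectable.

The default threshold is 0.5 on unit-depth trees, where root-to-tip
liability standard deviation is 1. That value was fixed once, on the
grounds that it yields cladistically plausible characters — a few state
changes per root-to-tip path, neither invariant (threshold too high) nor
randomized by toggling nearly every branch (threshold too low; saturation
also destroys the correlation signal between characters). Punctuational
runs use a larger threshold (1.5 in the analysis scripts) because every
branch contributes a full-variance increment.

Character distance is the polarity-free mismatch `min(m, 1-m)` where `m` is
the fraction of taxa at which two state columns disagree — simulated state
labels are arbitrary, so a character and its complement are identical
evidence. `pco_embed` is classical scaling (double-centering plus
eigendecomposition), dropping non-positive axes and reporting how many.
`correlated_pair_distance_test` compares within-block and between-block
pairwise distances (PCO-space by default; raw distances by flag — the
original description is ambiguous, so both are exposed). The statistic is
the Mann–Whitney U, but the p-value comes from permuting block labels over
characters: pairwise distances sharing a character are dependent, which
makes the textbook rank-sum reference distribution anticonservative (about
twice the nominal size in our null calibration), whereas the permutation
version is exact under character exchangeability. With within-block
correlation 0.9 on a 47-tip tree the test detects the structure in well
over 90% of replicates; with no correlation its rejection rate sits at the
nominal level.

## Comparative statistics

`pgls_corr` is generalized least squares under Brownian covariance from the
tree (Pagel's lambda fixed at 1 — the original names PGLS without model
selection), reporting the GLS correlation and a t-based p-value with n − 2
degrees of freedom; on a star phylogeny it reduces to the Pearson
correlation at machine precision, and it matches `nlme::gls` with a
Brownian correlation structure. Whether the original table reported
correlations or signed square roots of regression R² is not fully
specified; GLS correlations are reported. `correlation_table` lays out raw
correlations below and PGLS-corrected ones above the diagonal with a
significance-flag matrix at p < 0.01. Missing species are pruned from the
tree, never imputed.

## Reproducibility and numerics

Every stochastic operation takes a seed and derives an independent
substream from `(seed, operation tag)` via `substream_seed`, so pipelines
are reproducible end to end and adding a stage never perturbs another
stage's draws; callers combining many replicates should derive per-replicate
seeds with distinct tags so data-generation and permutation streams stay
decoupled. All seeds stay below 2^31. Other numeric conventions: symmetric
matrices are symmetrized before eigendecomposition; GPA convergence is
declared when the consensus moves less than 1e-10 in Frobenius norm (up to
1000 sweeps — maximally dispersed random shapes need a few hundred, real
landmark data a handful); zero-length branches are floored at 1e-9 in rate
estimation; equicorrelation admissibility `-1/(n-1) < r < 1` and block-PSD
constraints are enforced with informative errors.

## What the synthetic data do and do not show

The generator emulates the *structure* of the motivating datasets —
multi-species landmark samples (tens of species, ~16 specimens each, ~50
landmarks), correlation matrices whose integration spans the observed
0.19–0.46, trees at the sampled sizes — but not their content: synthetic
mean shapes are arbitrary configurations, within-species covariance is
Gaussian and stationary, trees are pure-birth, and integration enters
through stylized equicorrelation/block structures rather than the messier
empirical covariance fields of real crania. Passing tests therefore
establish that the *methods* behave as claimed (correct formulas, calibrated
tests, recoverable planted structure, mechanism-level effects with the
published signs and magnitudes where the mechanism forces them), not that
any empirical number from real specimens is reproduced. Headline empirical
quantities — particular RV values for Carnivora, specific module rate
means, tabulated disparity ratios for named matrices — are data-bound and
out of reach without the undeposited specimen data.

## Known limitations

* No sliding semilandmarks, missing-landmark estimation, or asymmetry
  decomposition in the Procrustes machinery.
* No exploratory module discovery; the RV framework is confirmatory only.
* The rate estimator is a Brownian weighted-squared-change method, not the
  adaptive-peak variable-rates algorithm of the original study; rate
  *levels* are comparable only within a run, though rank comparisons across
  modules — the quantity the analyses use — are robust to this substitution
  in simulation.
* Brownian motion only: no Ornstein–Uhlenbeck or early-burst models, and no
  selection regimes inside the tree walk (selection lives in the skewer
  machinery, one generation at a time).
* The threshold criterion, threshold magnitude and states-per-character of
  the original character simulations are unknown; conclusions here attach
  to the documented toggle dynamic.

## Problem sizes used by the shipped studies

The analysis scripts and acceptance checks run at the scales the motivating
study reports: 97-matrix panels with 1000 skewers each; 10-matrix ladders
with 1000 Brownian replicates per arm on 36-tip trees; 36 species × 16
specimens × 49 landmarks for the modularity tests; 47-tip trees with 30
characters in six blocks for the threshold study; 100–200 replicates for
power and calibration summaries. All complete in a few minutes on one CPU.
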