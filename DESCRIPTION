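Package: modmacro
Title: Phenotypic Integration, Modularity and Their Macroevolutionary Consequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for studying how phenotypic
    integration shapes macroevolution. Provides generalized Procrustes
    alignment of landmark configurations, pooled within-species covariance
    and congruence-coefficient correlation matrices, eigenvalue-dispersion
    and mean-squared-correlation integration indices, confirmatory RV
    coefficient tests of modular hypotheses with landmark-level permutation,
    random-skewers simulation of selection response (respondability,
    evolvability, conditional evolvability, flexibility, constraint),
    correlated versus uncorrelated Brownian-motion simulation of shape
    evolution on phylogenies with morphological disparity statistics,
    per-landmark evolutionary-rate estimation from weighted squared-change
    ancestral states with module-level rank tests, and threshold-model
    simulation of correlated discrete characters with principal-coordinates
    diagnostics. A synthetic-data module generates correlation matrices with
    controlled integration, multi-species landmark samples and pure-birth
    trees so every stage is testable without empirical specimen data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    phytools,
    nlme
Config/testthat/edition: 3
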