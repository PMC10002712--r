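Package: gwasconfound
Title: Forward-Time Simulation and Theory of Confounding in Population and
    Family-Based GWAS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A forward-time quantitative-genetics simulator with phase-tracked
    haplotypes, together with an estimator and theory suite, for quantifying
    how genetic confounding (assortative mating, population structure,
    admixture, stabilizing selection), sibling indirect effects, and
    gene-by-environment interactions bias effect-size estimates in
    population-based and within-family genome-wide association studies.
    Includes exact cis- and trans-linkage-disequilibrium computation on phased
    populations; population, sibling and parent-offspring (transmitted /
    untransmitted) GWAS estimators with their confound decompositions;
    polygenic-score regressions within families; closed-form predictions for
    biases under each confounding scenario (including the Bulmer equilibrium
    under Gaussian stabilizing selection); and config-driven desk-scale
    experiments with deterministic seeding.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
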