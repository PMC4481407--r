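Package: telofuse
Title: Null Models, Simulation and Inference for Drosophila Telomere Fusion Patterns
Version: 0.1.0
Authors@R:
    person("telofuse", "developers", email = "telofuse@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing which Drosophila melanogaster telomeres
    engage in end-to-end fusions in telomere-capping mutants. Provides the
    random-involvement null model for fused-telomere category frequencies and
    ring-Y expectations, a seeded Monte Carlo simulator of metaphase fusion
    patterns with a heterochromatin fusigenicity bias (including chain/ring
    topology derivation and STA/DTA labelling), chi-square goodness-of-fit
    and exact binomial ring-excess tests, maximum-likelihood estimation of
    the heterochromatin bias with bootstrap confidence intervals, and a
    small command-line interface over tab-separated count tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    optparse
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
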