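Package: mrmediate
Title: Summary-Data Mendelian Randomization Mediation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Causal mediation analysis from GWAS summary statistics using
    Mendelian randomization. Estimates the total, direct and indirect effects
    and the mediation proportion of an exposure-mediator-outcome triplet with
    eight estimators combining inverse-variance weighted, Egger and weighted
    median univariable and multivariable MR, including covariance-aware
    inference for the difference method, delta-method inference for the
    product method, and parametric bootstrap intervals for median-based
    methods. Ships utilities for reading and harmonizing summary statistics,
    double clumping of instrument sets against precomputed LD, and a
    simulation engine that generates individual-level data under configurable
    pleiotropy scenarios to evaluate accuracy and coverage of the estimators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
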