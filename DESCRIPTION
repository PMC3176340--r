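Package: pooldesign
Title: Optimal DNA Pooling Designs for Rare-Variant Detection by Resequencing
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Design calculator for detecting rare variants by sequencing
    pooled DNA samples. Computes the probability that a variant of given
    minor allele frequency is detected from a pool of k individuals at a
    given coverage depth and read-count threshold, under equal individual
    contributions (closed form) or contributions drawn from a symmetric
    Dirichlet prior (Monte Carlo over contributions with an exact inner
    genotype expectation). Provides optimal pool-size and lane-number
    searches, estimation of the contribution vector from pooled read counts
    plus individual genotypes, pseudo maximum-likelihood and pseudo
    method-of-moments estimators of the Dirichlet concentration, and
    sequencing-error calibration of the detection threshold under a
    multinomial error model, including randomized thresholds with exact
    false-call rate. A forward simulator of pooled sequencing serves as a
    brute-force oracle and synthetic-data generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    optparse,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
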