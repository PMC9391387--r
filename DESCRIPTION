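Package: cccausality
Title: Compression-Complexity Causality with Ordinal Patterns for Time
    Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", role = c("aut", "cre"),
           email = "author@example.org")
Description: Detects directed coupling between time series using
    compression-complexity causality (CCC) estimated with the
    effort-to-compress (ETC) complexity measure, and its permutation
    variant (PCCC) built on ordinal-pattern symbolization of
    delay-embedded series.  Also provides plug-in conditional mutual
    information estimators (scalar, condition-embedded and permutation
    CMI), AAFT and stationary-bootstrap surrogate significance testing, a
    coupled-Roessler benchmark generator with noise and missing-sample
    perturbations, and an experiment harness reporting true/false
    positive rates over realization ensembles.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
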