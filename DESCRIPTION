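Package: seqstack
Title: Sequential Stacking Link Prediction for Temporal Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Temporal link prediction by sequential stacking of static
    topological features. A bank of 41 per-layer network features (global,
    dyadic, low-rank spectral, and node-level) is concatenated across
    consecutive temporal layers and fed to a random forest that scores
    candidate dyads in a target layer, with or without partial observation
    of that layer. Includes two degree-corrected temporal stochastic block
    model simulators (community-label and edge-correlated), exact oracle
    AUC bounds by dyad enumeration, interpretable baselines (temporal
    common neighbors and per-feature time-series forecasting), balanced
    dyad sampling with stratified cross-validation folds, and evaluation
    utilities (AUC, precision-recall, Gini importance aggregation, and a
    synthetic benchmark runner).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    methods,
    ranger,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
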