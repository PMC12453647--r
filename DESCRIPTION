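Package: sepnet
Title: Deep Residual-Attention Networks for Early Sepsis Detection from
    Hourly Clinical Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for building and evaluating an hourly sepsis early-warning
    classifier from electronic-health-record style per-patient tables. The
    package provides a cohort container built on SummarizedExperiment, a
    leakage-safe preprocessing pipeline (forward/backward fill and mean
    imputation, z-score and min-max scaling, one-hot and label encoding,
    z-score outlier capping), a synthetic cohort simulator with controllable
    prevalence and pre-onset physiological drift, a convolutional classifier
    composed of multi-kernel dilated convolutions, sequential spatial and
    channel attention, hierarchically dilated blocks and residual chains with
    hand-derived backpropagation, an African vulture metaheuristic for
    hyperparameter search, and patient-wise splitting, cross-validation,
    ablation and metric reporting utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    yaml,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
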