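Package: bcgscreen
Title: Hypertension Screening from Ballistocardiogram Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for detecting hypertension from
    ballistocardiogram (BCG) recordings: a synthetic generator of
    mattress-sensor pressure signals with class-dependent heart-rate and
    amplitude shifts, a four-stage preprocessing chain (Butterworth
    high-/low-pass filtering, mean-plus-two-sigma anomaly removal,
    baseline correction, min-max normalisation), 30-second window
    statistical feature extraction, four classifier families (a fully
    connected + LSTM network, a Transformer encoder, stacking and
    soft-voting ensembles over random forest and gradient-boosted trees),
    and an evaluation harness with hold-out and stratified group-aware
    cross-validation, confusion-matrix metrics, Cohen's kappa, McNemar
    comparisons and ROC/AUC.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    randomForest,
    xgboost,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
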