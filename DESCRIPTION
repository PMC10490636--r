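Package: insoleweight
Title: Individualized Body-Weight Estimation from Smart Insole Sensor Data
Version: 0.1.0
Authors@R:
    person("M.", "Okafor", email = "m.okafor@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating human body weight from instrumented shoe
    insole (plantar pressure) recordings. Implements an automated adaptive
    bias correction for zero-inflated sensor channels (zero-reading and
    full additive modes), dynamic sliding-window segmentation with
    alpha-trimmed-mean aggregation, per-participant (personalized)
    extremely-randomized-trees regression, and a five-metric evaluation
    protocol (MAE, MSE, RMSE, R-squared, MAPE). Ships a reproducible
    synthetic insole-cohort generator emulating weight-proportional
    ground-reaction forces, participant-specific sensor load shares, and
    sensor dropout, plus a command-line interface for simulation, pipeline
    runs, and preprocessing ablations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    Rcpp,
    readxl,
    rlang,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
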