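Package: recurreval
Title: Fitting and Evaluating Prediction Models for Recurrent Clinical Events
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Fits four classes of prediction model for recurrent clinical
    events (negative binomial, zero-inflated negative binomial,
    Andersen-Gill, and Prentice-Williams-Peterson total-time counting-process
    Cox models), produces per-subject predicted event counts at a prediction
    horizon, and evaluates predictive performance with numerical measures
    (root mean squared prediction error, mean absolute prediction error,
    prediction bias, subgroup bias tables, deviance residuals) and graphical
    measures (count-calibration curves and Bland-Altman limits of
    agreement).  Includes data-preparation operators used in event-history
    epidemiology (event merging, count capping, constant-rate event-time
    imputation, counting-process conversion) and a synthetic cohort
    simulator (gamma-frailty Poisson process with structural zeros and
    administrative censoring) so the whole pipeline is testable without
    patient-level data.  A command-line interface wires simulation,
    preprocessing, fitting, prediction, evaluation and plotting into a
    reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    MASS,
    withr,
    data.table
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
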