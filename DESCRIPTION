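Package: cropcast
Title: Crop Production Forecasting with a Blending Ensemble of Regressors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for forecasting district-level crop production from
    seasonal weather averages and cultivation area. Provides a tabular
    dataset schema with CSV readers and validation, a cleaning pipeline
    (mean or neighbour imputation, plausibility filtering, duplicate and
    junk removal, min-max normalization), six benchmark regressors behind
    a uniform fit/predict contract, a blending ensemble that combines
    k-nearest-neighbour, random-forest and ridge base learners through a
    simplex-constrained meta-learner fitted on a held-out validation
    slice, a multi-phase repeated train/test evaluation harness with MAE,
    MSE, RMSE and R-squared, the Diebold-Mariano forecast-comparison
    test, a threshold-based crop recommender, and a seeded synthetic
    agro-climate data generator with stored ground truth for recovery
    testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    caret,
    e1071,
    randomForest,
    xgboost,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
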