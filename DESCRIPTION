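Package: fohem
Title: Fuzzy-Optimized Hybrid Ensemble Modelling for Intercrop Yield Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Predicts crop yield in maize-soybean intercropping systems by
    blending a Mamdani fuzzy inference system with a stacked machine-learning
    ensemble (random forest, gradient boosting, extreme learning machine).
    A genetic algorithm drives feature selection, feature engineering, and
    the optimization of the blend weights between the fuzzy and ensemble
    predictors, optionally per treatment-by-location group. Includes a
    seeded synthetic-data generator emulating the structure of intercropping
    field records, cross-validation and per-group evaluation utilities, and
    model-agnostic interpretability tools (permutation importance, sampling
    Shapley values, local linear surrogates).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
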