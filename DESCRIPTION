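Package: ridgetune
Title: Tuned and Pre-Specified Ridge Logistic Regression for Small or
    Sparse Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Penalized logistic regression for small or sparse
    binary-outcome data, built around the question of whether the ridge
    complexity parameter should be tuned from the data at all.  Provides
    exact Newton-Raphson estimators for maximum likelihood, Firth's
    bias-corrected logistic regression and its intercept-corrected
    variant (FLIC), and ridge logistic regression fitted either by direct
    penalized optimization or by Sullivan-Greenland data augmentation;
    complexity-parameter tuning by leave-one-out cross-validated
    deviance, generalized cross-validation, classification error,
    repeated 10-fold cross-validation and AIC, plus conversion of prior
    odds-ratio intervals into fixed penalties and oracle tuning
    benchmarks based on the true coefficients or event probabilities;
    separation detection by linear programming; a simulation framework
    generating correlated mixed-type covariates with calibrated marginal
    event rates; and calibration-focused performance evaluation
    (calibration slope, RMSD and MAD of log slopes, c-index, RMSE of
    coefficients and predictions).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    boot,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
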