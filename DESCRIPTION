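Package: hdweight
Title: Personalized Dry-Weight Supervision for Hemodialysis Patients
Version: 0.1.0
Authors@R:
    person("HD", "Weight Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Personalized post-dialysis weight forecasting for hemodialysis
    patients from electronic health record session logs. Detrends the
    post-dialysis weight series with an exponential moving average (EMA),
    models the residual (EMD, the EMA difference) with a global linear
    baseline plus a Gaussian-kernel locally weighted correction, and
    reconstructs the post-dialysis weight. Includes EHR-style CSV input
    and output, missing-weight imputation via the average weight draft,
    per-side outlier trimming, rolling-origin evaluation with a strict
    no-leakage protocol, an MAE/MAPE/MSE/r-squared metric suite, gamma
    error-distribution calibration with clinical 0.5 kg / 1 percent
    thresholds, one-way ANOVA and Holm-adjusted comparisons, a synthetic
    three-group hemodialysis cohort simulator, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
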