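Package: hisforecast
Title: Attention-Augmented LSTM Forecasting of Daily Health Improvement Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forecasts a self-reported daily Health Improvement Score (HIS,
    1-10 Likert) from multi-domain wearable time series (physiological,
    activity, sleep and body channels) with a stacked LSTM encoder, temporal
    attention over time steps, and a composite mean-squared-error plus
    temporal-smoothness loss, trained with Adam, DropConnect and early
    stopping. Includes a seeded synthetic wearable-cohort generator,
    windowing and normalization preprocessing, a Table-style hyperparameter
    grid search, a regression metric suite (MAE, RMSE, R2, EVS, MBE) with
    per-participant error distributions, persistence and autoregressive
    baselines, and beyond-horizon trajectory forecasting.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml,
    zoo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
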