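test_that("the metric suite matches its definitions and the brute-force oracle", {
  perfect <- compute_metrics(c(2, 4, 6), c(2, 4, 6))
  expect_equal(unlist(perfect), c(mae = 0, rmse = 0, r2 = 1, evs = 1, mbe = 0))

  # constant +1 shift: pins the R2 (biased) vs EVS (bias-blind) distinction
  shifted <- compute_metrics(c(1, 2, 3), c(2, 3, 4))
  expect_equal(shifted$mae, 1)
  expect_equal(shifted$rmse, 1)
  expect_equal(shifted$mbe, 1)
  expect_equal(shifted$r2, -0.5)
  expect_equal(shifted$evs, 1)

  set.seed(17)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    y <- rnorm(n, 5, 2)
    yhat <- y + rnorm(n, 0.2, 1)
    got <- compute_metrics(y, yhat)
    want <- oracle_metrics(y, yhat)
    for (m in names(want)) {
      expect_equal(got[[m]], want[[m]], tolerance = 1e-10)
    }
    expect_lte(got$mae, got$rmse) # Jensen
  }

  expect_warning(res <- compute_metrics(c(3, 3, 3), c(1, 2, 3)), "constant")
  expect_true(is.nan(res$r2) && is.nan(res$evs))
  expect_error(compute_metrics(1:3, 1:4), "equal length")
})

test_that("r2 equals evs exactly when the mean error is zero", {
  set.seed(23)
  for (i in 1:20) {
    y <- rnorm(30)
    e <- rnorm(30)
    e <- e - mean(e) # centred residuals -> mbe 0
    m <- compute_metrics(y, y + e)
    expect_equal(m$mbe, 0, tolerance = 1e-12)
    expect_equal(m$r2, m$evs, tolerance = 1e-12)
  }
})

test_that("per-participant evaluation groups and aggregates correctly", {
  # single participant: the distribution is the global metric set
  w1 <- manual_windows(y = normalize_his(c(4, 5, 6)), pid = rep(1, 3))
  pred_const <- function(w) matrix(normalize_his(5), dim(w$x)[1], 1)
  per <- evaluate_model(pred_const, w1)
  expect_equal(nrow(per), 1)
  global <- suppressWarnings(compute_metrics(c(4, 5, 6), rep(5, 3)))
  expect_equal(per$mae, global$mae)
  expect_equal(per$rmse, global$rmse)

  # perfect predictor: every participant at zero error
  w2 <- manual_windows(
    y = normalize_his(c(4, 5, 3, 6, 7, 2)), pid = rep(1:2, each = 3)
  )
  perfect <- function(w) w$y
  per2 <- evaluate_model(perfect, w2)
  expect_equal(per2$mae, c(0, 0))

  # 3-participant fixture: medians match hand-computed values
  y <- normalize_his(c(4, 5, 4, 6, 5, 6, 7, 8, 7))
  pid <- rep(1:3, each = 3)
  offs <- rep(c(0.9, 1.8, 2.7) / 9, each = 3) # +0.1/0.2/0.3 HIS per person
  w3 <- manual_windows(y = y, pid = pid)
  pred_off <- function(w) matrix(y + offs, ncol = 1)
  rep3 <- evaluate_models(list(off = pred_off), w3)
  med <- glance(rep3)
  expect_equal(med$mae, 1.8) # median of (0.9, 1.8, 2.7)
  expect_equal(med$mbe, 1.8)

  # a participant with a single window is excluded with a message
  w4 <- manual_windows(y = normalize_his(c(4, 5, 6)), pid = c(1, 1, 2))
  expect_message(per4 <- evaluate_model(perfect, w4), "< 2 test windows")
  expect_equal(per4$participant_id, 1)
})

test_that("evaluation reports are invariant to model order", {
  w <- manual_windows(
    y = normalize_his(runif(8, 3, 8)), pid = rep(1:2, each = 4)
  )
  a <- function(w) w$y + 0.01
  b <- function(w) w$y - 0.02
  r1 <- evaluate_models(list(a = a, b = b), w)
  r2 <- evaluate_models(list(b = b, a = a), w)
  sorted <- function(r) dplyr::arrange(tibble::as_tibble(r), model, participant_id, metric)
  expect_equal(sorted(r1), sorted(r2))
})

test_that("persistence predicts the window's final HIS value", {
  flat <- tiny_cohort(list(rep(5, 10), rep(7, 10)))
  wf <- make_windows(minmax_normalize(flat)$cohort, T = 3, H = 1)
  expect_equal(baseline_persistence(wf), wf$y)

  # linear ramp +delta/day: one-step persistence error is exactly delta
  delta <- 0.18
  ramp <- tiny_cohort(list(2 + delta * 0:14, 3 + delta * 0:14))
  wr <- make_windows(minmax_normalize(ramp)$cohort, T = 4, H = 1)
  per <- evaluate_model(
    external_baseline_adapter("persistence"), wr
  )
  expect_equal(per$mae, c(delta, delta), tolerance = 1e-10)

  # depends only on each window's final HIS value
  w_alt <- manual_windows(
    y = rep(0.5, 4), pid = rep(1, 4),
    his_lags = cbind(runif(4), runif(4), c(0.1, 0.2, 0.3, 0.4))
  )
  expect_equal(baseline_persistence(w_alt)[, 1], c(0.1, 0.2, 0.3, 0.4))
})

test_that("the linear AR baseline recovers autoregressive structure", {
  # noiseless AR(1): y_{d+1} = 0.8 y_d + 1.4, distinct starting levels
  phi <- 0.8
  const <- 1.4
  series <- lapply(seq(2, 8, length.out = 6), function(y0) {
    y <- numeric(12)
    y[1] <- y0
    for (d in 2:12) y[d] <- phi * y[d - 1] + const
    y
  })
  cohort <- tiny_cohort(series)
  w <- make_windows(minmax_normalize(cohort)$cohort, T = 4, H = 1)
  ar1 <- baseline_linear_ar(w, p = 1)
  # the slope survives the affine HIS normalization unchanged
  expect_equal(unname(ar1$fit$coefficients[2, 1]), phi, tolerance = 1e-6)
  expect_equal(predict(ar1, w), w$y, tolerance = 1e-8)

  # p = 0 predicts the training mean
  ar0 <- baseline_linear_ar(w, p = 0)
  expect_equal(
    predict(ar0, w)[, 1], rep(mean(w$y), nrow(w$y)),
    tolerance = 1e-12
  )

  # OLS normal equations: residuals orthogonal to the regressors
  set.seed(31)
  noisy <- tiny_cohort(lapply(1:5, function(i) runif(12, 2, 9)))
  wn <- make_windows(minmax_normalize(noisy)$cohort, T = 4, H = 1)
  ar3 <- baseline_linear_ar(wn, p = 3)
  resid <- wn$y - predict(ar3, wn)
  X <- cbind(1, wn$his_lags[, 2:4])
  expect_lt(max(abs(crossprod(X, resid))), 1e-8)
})

test_that("the adapter registry is transparent and rejects unknown names", {
  w <- manual_windows(
    y = runif(6), pid = rep(1:2, each = 3),
    his_lags = matrix(runif(18), 6, 3)
  )
  adapter <- external_baseline_adapter("persistence")
  expect_equal(predict(adapter, w), baseline_persistence(w))
  expect_error(
    external_baseline_adapter("prophet"),
    "unknown baseline.*persistence.*linear_ar.*lstm_plain"
  )
  custom <- external_baseline_adapter(
    "custom",
    predict_fn = function(w) matrix(0.5, dim(w$x)[1], 1)
  )
  expect_equal(predict(custom, w)[, 1], rep(0.5, 6))
})

test_that("the plain-LSTM adapter is the ablated configuration under the contract", {
  fx <- attention_fixture(n_windows = 24, T = 4, n_channels = 2, seed = 13)
  data <- list(train = fx, val = fx)
  plain <- external_baseline_adapter(
    "lstm_plain", data,
    train_cfg = train_config(max_epochs = 3, patience = 3, seed = 2)
  )
  expect_equal(plain$fit$config$lambda, 0)
  expect_equal(plain$fit$config$attention, "last")
  y <- predict(plain, fx)
  expect_equal(dim(y), c(24, 1))
})

test_that("beyond-horizon rollout obeys its contracts", {
  cohort <- generate_cohort(
    synthetic_config(n_participants = 6, seed = 19, missing_rate = 0)
  )
  data <- prepare_datasets(cohort, fractions = c(0.7, 0.3, 0), seed = 1)
  cfg <- model_config(
    n_channels = dim(data$train$x)[3], n_layers = 1, hidden_size = 6,
    dropout_rate = 0, dropconnect_rate = 0, T = 7, H = 1
  )
  fit <- train_his_model(
    data, cfg, train_config(max_epochs = 3, patience = 3, seed = 1)
  )

  one <- forecast_beyond(fit, cohort, 1, participants = 1)
  # base case: equals predicting on the final observed window
  norm <- minmax_normalize(forward_fill(cohort), fit$scalers)$cohort
  sub <- norm[norm$participant_id == 1, ]
  final_win <- as.matrix(
    sub[(nrow(sub) - 6):nrow(sub), intersect(schema_channels(), names(sub))]
  )
  direct <- predict_windows(final_win, fit$params, cfg)$y_hat[1, 1]
  expect_equal(one$his_pred, min(max(denormalize_his(direct), 1), 10))
  expect_equal(one$day, 32)

  traj <- forecast_beyond(fit, cohort, 30, participants = c(2, 3))
  expect_equal(nrow(traj), 60)
  expect_true(all(traj$his_pred >= 1 & traj$his_pred <= 10))
  expect_equal(unique(traj$day), 32:61)
  expect_error(forecast_beyond(fit, cohort, 0), "n_future_days")
  expect_s3_class(autoplot(traj), "ggplot")
})

test_that("tracked predictions align to their target days", {
  w <- manual_windows(y = normalize_his(c(5, 6)), pid = c(1, 1))
  w$index$start_day <- c(0L, 1L)
  tr <- track_predictions(function(w) w$y, w)
  expect_equal(tr$day, c(3, 4)) # start + T
  expect_equal(tr$actual, c(5, 6))
  expect_equal(tr$predicted, c(5, 6))
})

test_that("autoregressive-HIS mode feeds predictions back into the rollout", {
  cohort <- generate_cohort(
    synthetic_config(n_participants = 5, seed = 29, missing_rate = 0)
  )
  data <- prepare_datasets(cohort,
    fractions = c(0.8, 0.2, 0), seed = 2,
    include_his = TRUE
  )
  expect_true("his_lag" %in% data$train$channels)
  nc <- dim(data$train$x)[3]
  expect_equal(nc, nrow(feature_schema()) + 1)
  # the appended channel carries the window days' own normalized HIS
  expect_equal(data$train$x[, , nc], data$train$his_lags)

  cfg <- model_config(
    n_channels = nc, n_layers = 1, hidden_size = 6, dropout_rate = 0,
    dropconnect_rate = 0, T = 7, H = 1
  )
  fit <- train_his_model(
    data, cfg, train_config(max_epochs = 3, patience = 3, seed = 1)
  )
  traj <- forecast_beyond(fit, cohort, 10, participants = 1)
  expect_equal(nrow(traj), 10)
  expect_true(all(traj$his_pred >= 1 & traj$his_pred <= 10))
})
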