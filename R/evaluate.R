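#' Regression metric suite
#'
#' MAE, RMSE, coefficient of determination (R2), explained variance score
#' (EVS) and mean bias error (MBE) on the supplied scale. The error sign
#' convention is `e = y_pred - y_true`, so positive MBE means
#' over-prediction. `R2 = 1 - SSres/SStot` penalizes bias; `EVS = 1 -
#' Var(e)/Var(y)` does not, and the two coincide exactly when `MBE = 0`.
#'
#' @param y_true,y_pred Equal-length numeric vectors.
#' @return One-row tibble with columns `mae`, `rmse`, `r2`, `evs`, `mbe`.
#'   With constant `y_true`, `r2` and `evs` are `NaN` (with a warning).
#' @examples
#' compute_metrics(c(1, 2, 3), c(2, 3, 4)) # mae 1, r2 -0.5, evs 1
#' @export
compute_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("`y_true` and `y_pred` must have equal length", call. = FALSE)
  }
  e <- y_pred - y_true
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot == 0) {
    warning("constant y_true: R2 and EVS are undefined (NaN)", call. = FALSE)
    r2 <- NaN
    evs <- NaN
  } else {
    r2 <- 1 - sum(e^2) / ss_tot
    evs <- 1 - sum((e - mean(e))^2) / ss_tot
  }
  tibble::tibble(
    mae = mean(abs(e)), rmse = sqrt(mean(e^2)), r2 = r2, evs = evs,
    mbe = mean(e)
  )
}

new_predictor <- function(name, predict_fn, fit = NULL) {
  structure(list(name = name, predict_fn = predict_fn, fit = fit),
    class = "his_predictor"
  )
}

#' @export
print.his_predictor <- function(x, ...) {
  cat("<his_predictor> ", x$name, "\n", sep = "")
  invisible(x)
}

#' @export
predict.his_predictor <- function(object, windows, ...) {
  object$predict_fn(windows)
}

#' Persistence baseline
#'
#' Predicts every future step with the last HIS value observed inside the
#' window — the sanity floor any learned forecaster must beat.
#'
#' @param windows A `his_windows` object.
#' @return Matrix `(n, H)` of predictions on the normalized scale.
#' @export
baseline_persistence <- function(windows) {
  last <- windows$his_lags[, windows$T]
  matrix(last, nrow = length(last), ncol = windows$H)
}

#' Least-squares autoregressive baseline
#'
#' Ordinary least squares of the target on the window's last `p` HIS
#' values (plus intercept), fitted on training windows; `p = 0` predicts
#' the training mean. A numerically singular design falls back to a small
#' ridge penalty with a message. Stands in for classical univariate
#' baselines: it sees only the HIS history, none of the wearable
#' channels.
#'
#' @param train A `his_windows` object to fit on.
#' @param p Autoregressive order (0 to `T`).
#' @return A `his_predictor`.
#' @export
baseline_linear_ar <- function(train, p = 3) {
  p <- check_count(p, "p", 0L)
  if (p > train$T) stop("`p` cannot exceed the window length", call. = FALSE)
  design <- function(w) {
    if (p == 0) {
      matrix(1, dim(w$x)[1], 1)
    } else {
      cbind(1, w$his_lags[, (w$T - p + 1):w$T, drop = FALSE])
    }
  }
  X <- design(train)
  B <- tryCatch(
    {
      fit <- stats::lm.fit(X, train$y)
      if (any(is.na(fit$coefficients))) stop("singular design")
      as.matrix(fit$coefficients)
    },
    error = function(e) {
      message("linear AR design singular; refitting with ridge jitter 1e-6")
      solve(crossprod(X) + 1e-6 * diag(ncol(X)), crossprod(X, train$y))
    }
  )
  new_predictor("linear_ar", function(windows) design(windows) %*% B,
    fit = list(coefficients = B, p = p)
  )
}

baseline_registry <- function() {
  c("persistence", "linear_ar", "lstm_plain", "his_model")
}

#' Baseline adapter registry
#'
#' Uniform fit/predict contract over every comparison model so evaluation
#' treats them identically: `"persistence"`, `"linear_ar"`,
#' `"lstm_plain"` (the attention-ablated, `lambda = 0` configuration of
#' the HIS network — the in-package plain-LSTM baseline), and
#' `"his_model"` (the full proposed configuration). Published classical
#' and deep baselines (ARIMA, SARIMA, SVR, GRU, CNN-LSTM) can be attached
#' through the same contract when an implementation is supplied via
#' `predict_fn`; no internal re-implementation is shipped.
#'
#' @param name Registered baseline name, or any label when `predict_fn`
#'   is given.
#' @param data Training data as for [train_his_model()] (persistence
#'   ignores it).
#' @param ... Passed on (`p` for `linear_ar`; `config`/`train_cfg` for
#'   the network baselines).
#' @param predict_fn Optional external backend: a function
#'   `windows -> (n, H)` normalized predictions.
#' @return A `his_predictor`.
#' @export
external_baseline_adapter <- function(name, data = NULL, ...,
                                      predict_fn = NULL) {
  if (!is.null(predict_fn)) {
    return(new_predictor(name, predict_fn))
  }
  switch(name,
    persistence = new_predictor("persistence", baseline_persistence),
    linear_ar = baseline_linear_ar(data$train, ...),
    lstm_plain = {
      args <- list(...)
      cfg <- args$config %||% model_config(
        n_channels = dim(data$train$x)[3],
        n_layers = 2, hidden_size = 16,
        lambda = 0, attention = "last",
        T = data$train$T, H = data$train$H
      )
      cfg$lambda <- 0
      cfg$attention <- "last"
      fit <- train_his_model(data, cfg, args$train_cfg %||% train_config())
      new_predictor("lstm_plain", function(w) predict(fit, w)$y_hat, fit = fit)
    },
    his_model = {
      args <- list(...)
      fit <- train_his_model(data, args$config, args$train_cfg %||% train_config())
      new_predictor("his_model", function(w) predict(fit, w)$y_hat, fit = fit)
    },
    stop(
      "unknown baseline '", name, "'; registered: ",
      paste(baseline_registry(), collapse = ", "),
      call. = FALSE
    )
  )
}

predictor_yhat <- function(model, windows) {
  y <- if (inherits(model, "his_model_fit")) {
    predict(model, windows)$y_hat
  } else if (inherits(model, "his_predictor")) {
    model$predict_fn(windows)
  } else if (is.function(model)) {
    model(windows)
  } else {
    stop("unsupported model object of class ", class(model)[1], call. = FALSE)
  }
  matrix(y, nrow = dim(windows$x)[1])
}

#' Per-participant test metrics for one model
#'
#' Predictions are inverse-transformed to the 1-10 HIS scale and grouped
#' by participant; each participant contributes one [compute_metrics()]
#' row — the distribution the comparison boxplots summarize. Participants
#' with fewer than 2 test windows are excluded with a message.
#'
#' @param model A `his_model_fit`, `his_predictor`, or function
#'   `windows -> normalized predictions`.
#' @param windows Test `his_windows`.
#' @return Tibble: `participant_id` plus the five metric columns.
#' @export
evaluate_model <- function(model, windows) {
  if (dim(windows$x)[1] == 0) stop("no test windows", call. = FALSE)
  y_hat <- denormalize_his(predictor_yhat(model, windows))
  y <- denormalize_his(windows$y)
  pid <- windows$index$participant_id
  counts <- table(pid)
  small <- names(counts)[counts < 2]
  if (length(small) > 0) {
    message(
      "excluding ", length(small),
      " participant(s) with < 2 test windows from the metric distribution"
    )
  }
  keep <- setdiff(names(counts), small)
  purrr::map_dfr(keep, function(p) {
    rows <- pid == p
    dplyr::bind_cols(
      tibble::tibble(participant_id = utils::type.convert(p, as.is = TRUE)),
      compute_metrics(as.vector(y[rows, ]), as.vector(y_hat[rows, ]))
    )
  })
}

#' Compare several models on identical test windows
#'
#' @param models Named list of models (see [evaluate_model()]).
#' @param windows Test `his_windows`; every model sees the same windows.
#' @return A `his_eval_report`: long tibble `model, participant_id,
#'   metric, value` with a `medians` attribute (per-model metric
#'   medians).
#' @export
evaluate_models <- function(models, windows) {
  if (is.null(names(models)) || any(names(models) == "")) {
    stop("`models` must be a fully named list", call. = FALSE)
  }
  long <- purrr::imap_dfr(models, function(m, nm) {
    per <- evaluate_model(m, windows)
    tidyr::pivot_longer(per, -"participant_id",
      names_to = "metric", values_to = "value"
    ) |>
      dplyr::mutate(model = nm, .before = 1)
  })
  medians <- dplyr::summarise(
    dplyr::group_by(long, .data$model, .data$metric),
    median = stats::median(.data$value), .groups = "drop"
  )
  structure(long,
    class = c("his_eval_report", class(tibble::tibble())),
    medians = medians
  )
}

#' @export
tidy.his_eval_report <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.his_eval_report <- function(x, ...) {
  tidyr::pivot_wider(attr(x, "medians"),
    names_from = "metric", values_from = "median"
  )
}

#' Boxplots of per-participant metric distributions
#'
#' @param object A `his_eval_report`.
#' @param metrics Metrics to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.his_eval_report <- function(object,
                                     metrics = c("mae", "rmse", "r2", "evs", "mbe"),
                                     ...) {
  df <- dplyr::filter(tibble::as_tibble(object), .data$metric %in% metrics)
  ggplot2::ggplot(df, ggplot2::aes(.data$model, .data$value, fill = .data$model)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "Per-participant metric")
}

#' Track predictions against observed HIS
#'
#' One-step predictions aligned to their target day, on the 1-10 scale —
#' the in-sample trend view.
#'
#' @param model As for [evaluate_model()].
#' @param windows A `his_windows` object.
#' @return Tibble: `participant_id`, `day` (target day, 0-based),
#'   `actual`, `predicted`.
#' @export
track_predictions <- function(model, windows) {
  y_hat <- denormalize_his(predictor_yhat(model, windows))
  tibble::tibble(
    participant_id = windows$index$participant_id,
    day = windows$index$start_day + windows$T,
    actual = denormalize_his(windows$y[, 1]),
    predicted = y_hat[, 1]
  )
}

#' Forecast HIS beyond the observed period
#'
#' Iterative rollout from a participant's final observed window: each
#' step predicts the next day's HIS; future wearable covariates are
#' supplied by recycling the participant's last `T` observed days
#' cyclically. HIS is a target, not an input channel, by default, so
#' predictions do not feed back; for a model trained on windows built
#' with `include_his = TRUE` the rollout runs in autoregressive-HIS mode
#' and each predicted HIS becomes the `his_lag` input of the following
#' day. Outputs are inverse-transformed and clipped to the 1-10 scale.
#'
#' @param fit A trained `his_model_fit` (with scalers) or a predictor
#'   plus explicit `scalers`.
#' @param cohort A fully imputed `his_cohort` on the original scale.
#' @param n_future_days Days to forecast (>= 1).
#' @param participants Participant ids to roll out; default all.
#' @param scalers Override scalers (defaults to `fit$scalers`).
#' @return A tibble of class `his_forecast`: `participant_id`, `day`
#'   (continuing the observed 0-based index), `his_pred`.
#' @export
forecast_beyond <- function(fit, cohort, n_future_days,
                            participants = NULL, scalers = NULL) {
  check_count(n_future_days, "n_future_days", 1L)
  scalers <- scalers %||% fit$scalers
  if (is.null(scalers)) stop("no scalers available", call. = FALSE)
  config <- fit$config
  norm <- minmax_normalize(cohort, scalers)$cohort
  channels <- intersect(schema_channels(), names(norm))
  # one more input than wearable channels => the model was trained with
  # HIS as an input channel (autoregressive-HIS rollout)
  autoreg <- config$n_channels == length(channels) + 1L
  participants <- participants %||% unique(norm$participant_id)
  out <- purrr::map_dfr(participants, function(pid) {
    sub <- dplyr::arrange(norm[norm$participant_id == pid, ], .data$day)
    nd <- nrow(sub)
    if (nd < config$T) {
      stop(
        "participant ", pid, " has ", nd, " days; need >= T = ", config$T,
        call. = FALSE
      )
    }
    cov <- as.matrix(sub[channels])
    if (autoreg) cov <- cbind(cov, his_lag = normalize_his(sub$his))
    block <- cov[(nd - config$T + 1):nd, , drop = FALSE]
    ext <- cov
    preds <- numeric(n_future_days)
    for (k in seq_len(n_future_days)) {
      win <- ext[(nrow(ext) - config$T + 1):nrow(ext), , drop = FALSE]
      y <- predictor_yhat(fit, array_windows(win))[1, 1]
      preds[k] <- y
      nxt <- block[((k - 1) %% config$T) + 1, , drop = FALSE]
      if (autoreg) nxt[1, "his_lag"] <- y # predicted HIS feeds back
      ext <- rbind(ext, nxt)
    }
    tibble::tibble(
      participant_id = pid,
      day = max(sub$day) + seq_len(n_future_days),
      his_pred = pmin(pmax(denormalize_his(preds), 1), 10)
    )
  })
  structure(out, class = c("his_forecast", class(tibble::tibble())))
}

# Wrap a single T x C covariate window as a minimal his_windows.
array_windows <- function(win) {
  new_his_windows(
    x = array(win, c(1, dim(win))), y = matrix(0, 1, 1),
    index = tibble::tibble(participant_id = 0L, start_day = 0L),
    channels = colnames(win) %||% paste0("ch", seq_len(ncol(win))),
    T = nrow(win), H = 1L, stride = 1L, his_lags = matrix(0, 1, nrow(win))
  )
}

#' Plot forecast trajectories
#'
#' @param object A `his_forecast` tibble.
#' @param ... Unused.
#' @return A ggplot object (cohort mean with per-participant traces).
#' @export
autoplot.his_forecast <- function(object, ...) {
  df <- tibble::as_tibble(object)
  mean_df <- dplyr::summarise(
    dplyr::group_by(df, .data$day),
    his_pred = mean(.data$his_pred), .groups = "drop"
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$day, .data$his_pred)) +
    ggplot2::geom_line(
      ggplot2::aes(group = .data$participant_id),
      alpha = 0.25, colour = "steelblue"
    ) +
    ggplot2::geom_line(data = mean_df, linewidth = 1, colour = "black") +
    ggplot2::labs(x = "Day", y = "Predicted HIS")
}
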