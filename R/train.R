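flatten_params <- function(params) {
  unlist(unclass(params), use.names = FALSE)
}

unflatten_params <- function(flat, skeleton) {
  out <- utils::relist(flat, unclass(skeleton))
  class(out) <- class(skeleton)
  out
}

#' Training configuration
#'
#' @param learning_rate Adam step size (> 0); default 0.001.
#' @param batch_size Windows per gradient step; default 64.
#' @param max_epochs Upper bound on epochs; default 200.
#' @param patience Early-stopping patience in epochs (>= 1); default 10.
#' @param min_delta Minimum validation-loss drop that counts as an
#'   improvement; default 0.
#' @param seed Integer seed controlling initialization, shuffling and
#'   regularization masks.
#' @param checkpoint Optional file path; the best model is saved there.
#' @return A list of class `his_train_config`.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 64,
                         max_epochs = 200, patience = 10, min_delta = 0,
                         seed = 1, checkpoint = NULL) {
  if (!is.numeric(learning_rate) || learning_rate <= 0) {
    stop("`learning_rate` must be > 0", call. = FALSE)
  }
  check_count(batch_size, "batch_size", 1L)
  check_count(max_epochs, "max_epochs", 1L)
  check_count(patience, "patience", 1L)
  structure(
    list(
      learning_rate = learning_rate, batch_size = as.integer(batch_size),
      max_epochs = as.integer(max_epochs), patience = as.integer(patience),
      min_delta = min_delta, seed = as.integer(seed), checkpoint = checkpoint
    ),
    class = "his_train_config"
  )
}

new_train_state <- function() {
  list(
    epoch = 0L, best_val_loss = Inf, best_epoch = 0L,
    epochs_since_improvement = 0L, stopped_early = FALSE,
    val_history = numeric()
  )
}

#' Early-stopping state update
#'
#' Registers one epoch's validation loss: an improvement
#' (`val_loss < best_val_loss - min_delta`) resets the non-improvement
#' counter, otherwise it increments; the stop flag is raised once the
#' counter reaches `patience`.
#'
#' @param state State list as produced by previous calls (or a fresh
#'   training run).
#' @param val_loss This epoch's validation loss.
#' @param patience Epochs without improvement tolerated before stopping.
#' @param min_delta Improvement threshold; default 0.
#' @return The updated state; `$improved` marks whether this epoch set a
#'   new best.
#' @export
early_stopping_update <- function(state, val_loss, patience, min_delta = 0) {
  state$epoch <- state$epoch + 1L
  state$val_history <- c(state$val_history, val_loss)
  if (val_loss < state$best_val_loss - min_delta) {
    state$best_val_loss <- val_loss
    state$best_epoch <- state$epoch
    state$epochs_since_improvement <- 0L
    state$improved <- TRUE
  } else {
    state$epochs_since_improvement <- state$epoch - state$best_epoch
    state$improved <- FALSE
  }
  if (state$epochs_since_improvement >= patience) state$stopped_early <- TRUE
  state
}

adam_init <- function(n) {
  list(m = numeric(n), v = numeric(n), t = 0L)
}

adam_step <- function(theta, grad, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  opt$m <- beta1 * opt$m + (1 - beta1) * grad
  opt$v <- beta2 * opt$v + (1 - beta2) * grad^2
  m_hat <- opt$m / (1 - beta1^opt$t)
  v_hat <- opt$v / (1 - beta2^opt$t)
  list(theta = theta - lr * m_hat / (sqrt(v_hat) + eps), opt = opt)
}

#' Train the HIS model
#'
#' Minimizes the composite loss with Adam over mini-batches built
#' time-ordered within participant (so the cross-window smoothness term
#' is well-defined for a one-step horizon), monitors validation loss —
#' computed with the same `lambda` term — every epoch, stops early after
#' `patience` epochs without improvement, and returns the parameters from
#' the best-validation epoch.
#'
#' @param data Output of [prepare_datasets()], or any list with `train`
#'   and `val` `his_windows` (plus optional `scalers`).
#' @param config A [model_config()]; `NULL` derives one from the data
#'   with default settings.
#' @param train_cfg A [train_config()].
#' @return A `his_model_fit`: best `params`, `config`, `train_cfg`,
#'   per-epoch `history` tibble, early-stopping `state`, `scalers`.
#' @export
train_his_model <- function(data, config = NULL, train_cfg = train_config()) {
  train <- data$train
  val <- data$val
  if (is.null(train) || dim(train$x)[1] == 0) {
    stop("training split is empty", call. = FALSE)
  }
  if (is.null(val) || dim(val$x)[1] == 0) {
    stop("validation split is empty", call. = FALSE)
  }
  if (is.null(config)) {
    config <- model_config(
      n_channels = dim(train$x)[3], T = train$T, H = train$H
    )
  }
  params <- init_params(config, seed = train_cfg$seed)
  theta <- flatten_params(params)
  opt <- adam_init(length(theta))
  state <- new_train_state()
  best_theta <- theta
  history <- list()
  n_train <- dim(train$x)[1]
  val_groups <- val$index$participant_id

  with_seed(train_cfg$seed + 1L, {
    for (epoch in seq_len(train_cfg$max_epochs)) {
      # shuffle participants, keep each one's windows in time order
      pids <- unique(train$index$participant_id)
      order_rows <- unlist(lapply(
        sample(pids),
        function(p) which(train$index$participant_id == p)
      ), use.names = FALSE)
      batch_starts <- seq(1L, n_train, by = train_cfg$batch_size)
      epoch_losses <- numeric(length(batch_starts))
      for (bi in seq_along(batch_starts)) {
        rows <- order_rows[
          batch_starts[bi]:min(batch_starts[bi] + train_cfg$batch_size - 1L, n_train)
        ]
        params <- unflatten_params(theta, params)
        res <- model_loss_grad(
          train$x[rows, , , drop = FALSE], train$y[rows, , drop = FALSE],
          params, config,
          mode = "train",
          groups = train$index$participant_id[rows]
        )
        if (!is.finite(res$loss)) {
          stop(
            "non-finite training loss at epoch ", epoch, ", batch ", bi,
            " (learning rate ", train_cfg$learning_rate, ")",
            call. = FALSE
          )
        }
        epoch_losses[bi] <- res$loss
        step <- adam_step(
          theta, flatten_params(res$grads), opt, train_cfg$learning_rate
        )
        theta <- step$theta
        opt <- step$opt
      }
      params <- unflatten_params(theta, params)
      val_fwd <- model_forward(val$x, params, config, mode = "eval")
      val_loss <- composite_loss(
        val$y, val_fwd$y_hat, config$lambda, val_groups
      )
      state <- early_stopping_update(
        state, val_loss, train_cfg$patience, train_cfg$min_delta
      )
      if (isTRUE(state$improved)) best_theta <- theta
      history[[epoch]] <- tibble::tibble(
        epoch = epoch, train_loss = mean(epoch_losses), val_loss = val_loss
      )
      if (state$stopped_early) break
    }
  })

  fit <- structure(
    list(
      params = unflatten_params(best_theta, params), config = config,
      train_cfg = train_cfg, history = dplyr::bind_rows(history),
      state = state, scalers = data$scalers
    ),
    class = "his_model_fit"
  )
  if (!is.null(train_cfg$checkpoint)) save_checkpoint(fit, train_cfg$checkpoint)
  fit
}

#' @export
print.his_model_fit <- function(x, ...) {
  cat(
    "<his_model_fit> L=", x$config$n_layers, " hidden=", x$config$hidden_size,
    " lambda=", x$config$lambda, " attention=", x$config$attention,
    "\n  epochs run: ", x$state$epoch, " (best epoch ", x$state$best_epoch,
    ", best val loss ", signif(x$state$best_val_loss, 5),
    if (x$state$stopped_early) ", stopped early" else "", ")\n",
    sep = ""
  )
  invisible(x)
}

#' Predict from a fitted model
#'
#' @param object A `his_model_fit`.
#' @param windows A `his_windows` object (or array).
#' @param ... Unused.
#' @return A `his_prediction` (see [predict_windows()]).
#' @export
predict.his_model_fit <- function(object, windows, ...) {
  predict_windows(windows, object$params, object$config)
}

#' Tidy the training history of a fit
#'
#' @param x A `his_model_fit`.
#' @param ... Unused.
#' @return Tibble with `epoch`, `train_loss`, `val_loss`.
#' @export
tidy.his_model_fit <- function(x, ...) x$history

#' One-row summary of a fit
#'
#' @param x A `his_model_fit`.
#' @param ... Unused.
#' @return Tibble with epochs run, best epoch/loss, early-stop flag and
#'   parameter count.
#' @export
glance.his_model_fit <- function(x, ...) {
  tibble::tibble(
    epochs = x$state$epoch,
    best_epoch = x$state$best_epoch,
    best_val_loss = x$state$best_val_loss,
    stopped_early = x$state$stopped_early,
    n_params = n_params(x$params),
    lambda = x$config$lambda
  )
}

#' Plot training and validation loss curves
#'
#' @param object A `his_model_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.his_model_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$history, c("train_loss", "val_loss"),
    names_to = "series", values_to = "loss"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$epoch, .data$loss, colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(
      xintercept = object$state$best_epoch, linetype = "dashed",
      colour = "grey40"
    ) +
    ggplot2::labs(x = "Epoch", y = "Composite loss", colour = NULL)
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single versioned file holding the configuration, the
#' best parameters, the training settings, the normalization scalers and
#' the training history; a JSON sidecar (`<path>.json`) exposes the
#' configuration for inspection. Loading restores a fit whose predictions
#' are bit-identical to the saved model's.
#'
#' @param fit A `his_model_fit`.
#' @param path Checkpoint file path.
#' @return `save_checkpoint()` returns `path` invisibly;
#'   `load_checkpoint()` returns the restored `his_model_fit`.
#' @export
save_checkpoint <- function(fit, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  saveRDS(list(version = 1L, fit = unclass(fit)), path)
  sidecar <- c(
    unclass(fit$config),
    list(
      seed = fit$train_cfg$seed, best_epoch = fit$state$best_epoch,
      best_val_loss = fit$state$best_val_loss
    )
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$version, 1L)) {
    stop("unsupported checkpoint version: ", obj$version, call. = FALSE)
  }
  fit <- obj$fit
  class(fit$config) <- "his_model_config"
  class(fit$params) <- "his_model_params"
  structure(fit, class = "his_model_fit")
}

#' Hyperparameter grid
#'
#' The tuning grid over model depth, width, learning rate, dropout and
#' batch size (432 combinations at the defaults).
#'
#' @param n_layers,hidden_size,learning_rate,dropout_rate,batch_size
#'   Candidate values (non-empty).
#' @return A list of class `his_grid_spec`.
#' @export
grid_spec <- function(n_layers = c(3, 4, 5, 6),
                      hidden_size = c(64, 128, 256),
                      learning_rate = c(0.0001, 0.001, 0.01),
                      dropout_rate = c(0.1, 0.2, 0.3, 0.4),
                      batch_size = c(32, 64, 128)) {
  fields <- list(
    n_layers = n_layers, hidden_size = hidden_size,
    learning_rate = learning_rate, dropout_rate = dropout_rate,
    batch_size = batch_size
  )
  if (any(lengths(fields) == 0)) {
    stop("grid lists must be non-empty", call. = FALSE)
  }
  structure(fields, class = "his_grid_spec")
}

#' Enumerate a grid
#'
#' @param grid A [grid_spec()].
#' @return Tibble of all combinations, in enumeration order.
#' @export
enumerate_grid <- function(grid) {
  tibble::as_tibble(expand.grid(unclass(grid),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  ))
}

#' Grid search over model hyperparameters
#'
#' Trains one model per grid combination (optionally a seeded random
#' subset, for desk-scale runs) and ranks combinations by best validation
#' loss. Ties break toward fewer parameters, then earlier enumeration
#' order. A combination whose training fails is recorded with `NA` loss
#' and skipped, never fatal.
#'
#' @param grid A [grid_spec()].
#' @param data As for [train_his_model()].
#' @param train_cfg Template [train_config()]; each combination overrides
#'   its learning rate and batch size.
#' @param subset Optional number of combinations to sample (seeded).
#' @param lambda,attention Passed to each [model_config()].
#' @param seed Seed for subset sampling.
#' @return List with `best_config`, `best_train_cfg`, `best_fit`, and the
#'   full `leaderboard` tibble.
#' @export
grid_search <- function(grid, data, train_cfg = train_config(), subset = NULL,
                        lambda = 0.1, attention = "softmax", seed = 1) {
  combos <- enumerate_grid(grid)
  combos$order <- seq_len(nrow(combos))
  if (!is.null(subset) && subset < nrow(combos)) {
    combos <- with_seed(seed, combos[sort(sample(nrow(combos), subset)), ])
  }
  fits <- vector("list", max(combos$order))
  rows <- purrr::pmap(combos, function(n_layers, hidden_size, learning_rate,
                                       dropout_rate, batch_size, order) {
    cfg <- model_config(
      n_channels = dim(data$train$x)[3], n_layers = n_layers,
      hidden_size = hidden_size, dropout_rate = dropout_rate,
      dropconnect_rate = dropout_rate, lambda = lambda,
      attention = attention, T = data$train$T, H = data$train$H
    )
    tc <- train_cfg
    tc$learning_rate <- learning_rate
    tc$batch_size <- as.integer(batch_size)
    fit <- tryCatch(train_his_model(data, cfg, tc), error = function(e) e)
    if (inherits(fit, "error")) {
      return(tibble::tibble(
        n_layers = n_layers, hidden_size = hidden_size,
        learning_rate = learning_rate, dropout_rate = dropout_rate,
        batch_size = batch_size, order = order,
        val_loss = NA_real_, n_params = NA_integer_,
        error = conditionMessage(fit)
      ))
    }
    fits[[order]] <<- fit
    tibble::tibble(
      n_layers = n_layers, hidden_size = hidden_size,
      learning_rate = learning_rate, dropout_rate = dropout_rate,
      batch_size = batch_size, order = order,
      val_loss = fit$state$best_val_loss, n_params = n_params(fit$params),
      error = NA_character_
    )
  })
  leaderboard <- dplyr::arrange(
    dplyr::bind_rows(rows),
    is.na(.data$val_loss), .data$val_loss, .data$n_params, .data$order
  )
  if (all(is.na(leaderboard$val_loss))) {
    stop("every grid combination failed to train", call. = FALSE)
  }
  best <- leaderboard[1, ]
  best_fit <- fits[[best$order]]
  list(
    best_config = best_fit$config, best_train_cfg = best_fit$train_cfg,
    best_fit = best_fit, leaderboard = leaderboard
  )
}
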