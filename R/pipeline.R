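#' Default pipeline configuration
#'
#' The resolved settings `run_pipeline()` uses when a stage-specific value
#' is absent from the supplied config (a YAML file or nested list with
#' optional `simulate`, `preprocess`, `train`, `evaluate`, `forecast`
#' blocks).
#'
#' @return Nested list of defaults.
#' @export
default_pipeline_config <- function() {
  list(
    simulate = list(n_participants = 384, n_days = 32, missing_rate = 0.05),
    preprocess = list(
      window = 7, stride = 1, horizon = 1,
      fractions = c(0.70, 0.15, 0.15), threshold = 0.2
    ),
    train = list(
      n_layers = 5, hidden_size = 128, dropout_rate = 0.2,
      dropconnect_rate = 0.2, lambda = 0.1, learning_rate = 0.001,
      batch_size = 64, max_epochs = 200, patience = 10
    ),
    tune = list(subset = 8),
    evaluate = list(baselines = c("persistence", "linear_ar")),
    forecast = list(days = 30)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      merge_config(base[[nm]], override[[nm]])
    } else {
      override[[nm]]
    }
  }
  base
}

read_pipeline_config <- function(config) {
  user <- if (is.null(config)) {
    list()
  } else if (is.character(config)) {
    yaml::read_yaml(config)
  } else {
    config
  }
  defaults <- default_pipeline_config()
  bad <- setdiff(names(user), names(defaults))
  if (length(bad) > 0) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  for (sec in names(user)) {
    bad <- setdiff(names(user[[sec]]), names(defaults[[sec]]))
    if (length(bad) > 0) {
      stop(
        "unknown config key(s) in '", sec, "': ", paste(bad, collapse = ", "),
        call. = FALSE
      )
    }
  }
  merge_config(defaults, user)
}

write_manifest <- function(dir, command, config, seed, inputs = NULL) {
  manifest <- list(
    command = command, config = config, seed = seed,
    inputs = inputs, out = dir,
    package_version = as.character(utils::packageVersion("hisforecast")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(manifest)
}

require_artifact <- function(path, producer) {
  if (!file.exists(path)) {
    stop(
      "missing upstream artifact '", path, "'; run the '", producer,
      "' stage first",
      call. = FALSE
    )
  }
  path
}

#' Run pipeline stages end to end
#'
#' Executes the requested stages in order — `simulate`, `preprocess`,
#' `train`, `tune`, `evaluate`, `forecast` — each reading only the
#' previous stage's outputs under `out_dir` and writing its own artifacts
#' plus a manifest. One root seed fans out to fixed per-stage sub-seeds
#' (see [derive_seed()] in the sources), so any stage is independently
#' reproducible.
#'
#' @param stages Character vector of stage names, in execution order.
#' @param out_dir Artifact directory.
#' @param config `NULL`, a YAML path, or a nested list (see
#'   [default_pipeline_config()]).
#' @param seed Root integer seed.
#' @return Invisibly, a named list of per-stage results.
#' @export
run_pipeline <- function(stages, out_dir, config = NULL, seed = 1) {
  cfg <- read_pipeline_config(config)
  known <- c("simulate", "preprocess", "train", "tune", "evaluate", "forecast")
  bad <- setdiff(stages, known)
  if (length(bad) > 0) {
    stop(
      "unknown stage(s): ", paste(bad, collapse = ", "),
      " (known: ", paste(known, collapse = ", "), ")",
      call. = FALSE
    )
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  for (stage in stages) {
    results[[stage]] <- run_stage(stage, out_dir, cfg, seed)
  }
  invisible(results)
}

#' @rdname run_pipeline
#' @param stage A single stage name.
#' @export
run_stage <- function(stage, out_dir, config, seed) {
  cfg <- read_pipeline_config(config)
  s_seed <- derive_seed(seed, stage)
  switch(stage,
    simulate = {
      sc <- cfg$simulate
      cohort <- generate_cohort(synthetic_config(
        n_participants = sc$n_participants, n_days = sc$n_days,
        missing_rate = sc$missing_rate, seed = s_seed
      ))
      dir <- file.path(out_dir, "cohort")
      write_cohort(cohort, dir)
      write_manifest(dir, "simulate", sc, seed)
      cohort
    },
    preprocess = {
      pc <- cfg$preprocess
      cohort <- read_cohort(require_artifact(
        file.path(out_dir, "cohort", "channels.csv"), "simulate"
      ) |> dirname())
      data <- prepare_datasets(cohort,
        T = pc$window, stride = pc$stride, H = pc$horizon,
        fractions = unlist(pc$fractions), seed = s_seed,
        threshold = pc$threshold
      )
      dir <- file.path(out_dir, "preprocessed")
      dir.create(dir, showWarnings = FALSE)
      saveRDS(data, file.path(dir, "windows.rds"))
      readr::write_csv(
        dplyr::bind_rows(
          train = data$train$index,
          val = if (!is.null(data$val)) data$val$index,
          test = if (!is.null(data$test)) data$test$index,
          .id = "split"
        ),
        file.path(dir, "index.csv")
      )
      jsonlite::write_json(data$scalers, file.path(dir, "scalers.json"),
        digits = NA
      )
      write_manifest(dir, "preprocess", pc, seed)
      data
    },
    train = {
      tc <- cfg$train
      data <- readRDS(require_artifact(
        file.path(out_dir, "preprocessed", "windows.rds"), "preprocess"
      ))
      mc <- model_config(
        n_channels = dim(data$train$x)[3], n_layers = tc$n_layers,
        hidden_size = tc$hidden_size, dropout_rate = tc$dropout_rate,
        dropconnect_rate = tc$dropconnect_rate, lambda = tc$lambda,
        T = data$train$T, H = data$train$H
      )
      dir <- file.path(out_dir, "model")
      dir.create(dir, showWarnings = FALSE)
      fit <- train_his_model(data, mc, train_config(
        learning_rate = tc$learning_rate, batch_size = tc$batch_size,
        max_epochs = tc$max_epochs, patience = tc$patience, seed = s_seed,
        checkpoint = file.path(dir, "checkpoint.rds")
      ))
      readr::write_lines(
        purrr::pmap_chr(fit$history, function(epoch, train_loss, val_loss) {
          jsonlite::toJSON(
            list(epoch = epoch, train_loss = train_loss, val_loss = val_loss),
            auto_unbox = TRUE, digits = NA
          )
        }),
        file.path(dir, "training_log.jsonl")
      )
      write_manifest(dir, "train", tc, seed)
      fit
    },
    tune = {
      data <- readRDS(require_artifact(
        file.path(out_dir, "preprocessed", "windows.rds"), "preprocess"
      ))
      tc <- cfg$train
      res <- grid_search(
        grid_spec(), data,
        train_config(
          max_epochs = tc$max_epochs, patience = tc$patience, seed = s_seed
        ),
        subset = cfg$tune$subset, seed = s_seed
      )
      dir <- file.path(out_dir, "tune")
      dir.create(dir, showWarnings = FALSE)
      readr::write_csv(res$leaderboard, file.path(dir, "leaderboard.csv"))
      write_manifest(dir, "tune", cfg$tune, seed)
      res
    },
    evaluate = {
      data <- readRDS(require_artifact(
        file.path(out_dir, "preprocessed", "windows.rds"), "preprocess"
      ))
      fit <- load_checkpoint(require_artifact(
        file.path(out_dir, "model", "checkpoint.rds"), "train"
      ))
      models <- c(
        list(his_model = fit),
        stats::setNames(
          lapply(
            cfg$evaluate$baselines,
            function(b) external_baseline_adapter(b, data)
          ),
          cfg$evaluate$baselines
        )
      )
      report <- evaluate_models(models, data$test)
      dir <- file.path(out_dir, "report")
      dir.create(dir, showWarnings = FALSE)
      readr::write_csv(tibble::as_tibble(report), file.path(dir, "metrics.csv"))
      readr::write_csv(glance(report), file.path(dir, "medians.csv"))
      jsonlite::write_json(glance(report), file.path(dir, "medians.json"),
        digits = NA
      )
      write_manifest(dir, "evaluate", cfg$evaluate, seed)
      report
    },
    forecast = {
      fit <- load_checkpoint(require_artifact(
        file.path(out_dir, "model", "checkpoint.rds"), "train"
      ))
      cohort <- read_cohort(require_artifact(
        file.path(out_dir, "cohort", "channels.csv"), "simulate"
      ) |> dirname())
      cohort <- forward_fill(cohort)
      traj <- forecast_beyond(fit, cohort, cfg$forecast$days)
      dir <- file.path(out_dir, "forecast")
      dir.create(dir, showWarnings = FALSE)
      readr::write_csv(traj, file.path(dir, "trajectories.csv"))
      write_manifest(dir, "forecast", cfg$forecast, seed)
      traj
    },
    stop("unknown stage '", stage, "'", call. = FALSE)
  )
}
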