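#' Synthetic cohort configuration
#'
#' Settings for the seeded wearable-cohort simulator. Defaults emulate the
#' study design the package targets: 384 participants followed for 32 days,
#' each day contributing a 21-channel wearable record
#' (see [feature_schema()]) and a self-reported Health Improvement Score
#' (HIS) on a 1-10 scale. Population HIS follows [latent_his_trajectory()]
#' (initial improvement, a slight mid-study dip, then a resumed climb with
#' diminishing gains); individual days fluctuate around it through an
#' autocorrelated daily "wellness" process that also moves the wearable
#' channels, so the channels carry learnable signal about upcoming HIS.
#'
#' @param n_participants Number of participants (>= 0).
#' @param n_days Days per participant (>= 2).
#' @param seed Integer seed; the cohort is a pure function of the config.
#' @param trend Latent trajectory parameters, see [trend_params()].
#' @param noise_sd Named numeric vector of per-channel noise standard
#'   deviations (in each channel's units) plus `"his"`; entries override
#'   the built-in defaults.
#' @param missing_rate Fraction of channel cells set missing uniformly at
#'   random, in `[0, 1)`. HIS itself is never masked.
#' @param wellness List with `rho` (day-to-day autocorrelation), `sd`
#'   (stationary standard deviation) and `gain` (HIS units per wellness
#'   unit) of the shared daily wellness process.
#' @param events List describing acute strain events (an overexertion or
#'   poor-recovery day): `rate` — per participant-day probability;
#'   `his_drop` — peak HIS depression in HIS units; `lag_profile` —
#'   relative depression at lags 1, 2, ... days after the event
#'   (default peaks at lag 3, mimicking delayed-onset fatigue, which
#'   peaks 48-72 h after overexertion). On the event day itself heart
#'   rate, respiration and sleep disruption jump, so the wearable
#'   channels flag the event days before it reaches the self-report.
#'   `rate = 0` disables events.
#' @param spike_events Optional tibble/data frame with columns
#'   `participant`, `day` (0-based), `channel`, `magnitude`: planted
#'   anomalies added to the named channel. Off by default; used to build
#'   attention test fixtures.
#' @param round_his If `TRUE`, HIS is rounded to integers to mimic Likert
#'   reporting; default keeps the real-valued regression target.
#' @return A validated list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_participants = 384, n_days = 32, seed = 1,
                             trend = trend_params(), noise_sd = NULL,
                             missing_rate = 0.05,
                             wellness = list(rho = 0.7, sd = 0.6, gain = 0.8),
                             events = list(
                               rate = 0.08, his_drop = 1.2,
                               lag_profile = c(0.15, 0.5, 1, 0.4)
                             ),
                             spike_events = NULL, round_his = FALSE) {
  check_count(n_participants, "n_participants", min = 0L)
  check_count(n_days, "n_days", min = 2L)
  check_fraction(missing_rate, "missing_rate")
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  sd_default <- default_noise_sd()
  if (!is.null(noise_sd)) {
    bad <- setdiff(names(noise_sd), names(sd_default))
    if (length(bad) > 0) {
      stop("`noise_sd` has unknown channels: ", paste(bad, collapse = ", "),
        call. = FALSE
      )
    }
    if (any(noise_sd < 0)) stop("`noise_sd` must be >= 0", call. = FALSE)
    sd_default[names(noise_sd)] <- noise_sd
  }
  if (!is.null(spike_events)) {
    spike_events <- tibble::as_tibble(spike_events)
    need <- c("participant", "day", "channel", "magnitude")
    if (!all(need %in% names(spike_events))) {
      stop("`spike_events` needs columns ", paste(need, collapse = ", "),
        call. = FALSE
      )
    }
    if (!all(spike_events$channel %in% schema_channels())) {
      stop("`spike_events` names unknown channels", call. = FALSE)
    }
  }
  structure(
    list(
      n_participants = as.integer(n_participants),
      n_days = as.integer(n_days), seed = as.integer(seed), trend = trend,
      noise_sd = sd_default, missing_rate = missing_rate,
      wellness = wellness, events = events, spike_events = spike_events,
      round_his = isTRUE(round_his)
    ),
    class = "synthetic_config"
  )
}

default_noise_sd <- function() {
  c(
    hr_rest = 2, hr_active = 5, hrv = 6, spo2 = 0.6, resp_rate = 0.8,
    body_temp = 0.15, steps = 1200, step_intensity = 0.2, distance = 0.3,
    calories = 150, active_minutes = 10, sitting_frac = 0.8,
    standing_frac = 0.6, lying_frac = 0.5, sleep_hours = 0.7,
    deep_frac = 0.03, light_frac = 0.04, rem_frac = 0.03,
    interruptions = 1, weight = 0.25, bmi = 0, his = 0.5
  )
}

#' Generate a synthetic wearable cohort
#'
#' Simulates `n_participants` day-indexed records under the configured
#' latent HIS trajectory and shared wellness process. Channels are coupled
#' to latent fitness with physiologically signed effects (resting heart
#' rate falls, steps and HRV rise as fitness improves); sleep-phase
#' fractions sum to one, SpO2 stays in [85, 100], HIS is clipped to
#' [1, 10]. Missing channel cells (never HIS) are injected uniformly at
#' random at `missing_rate` and appear as `NA`.
#'
#' @param config A [synthetic_config()].
#' @return A `his_cohort` tibble with one row per participant-day: columns
#'   `participant_id`, `day` (0-based), the 21 schema channels, and `his`.
#'   Attributes: `participants` (id, sex, age), `latent` (the noise-free
#'   latent trajectory per participant-day), `schema`, and `config`.
#' @examples
#' cohort <- generate_cohort(synthetic_config(n_participants = 4, seed = 1))
#' dplyr::count(cohort, participant_id)
#' @export
generate_cohort <- function(config = synthetic_config()) {
  if (!inherits(config, "synthetic_config")) {
    stop("`config` must come from synthetic_config()", call. = FALSE)
  }
  np <- config$n_participants
  nd <- config$n_days
  sch <- feature_schema()
  if (np == 0L) {
    empty <- tibble::as_tibble(c(
      list(participant_id = integer(), day = integer()),
      stats::setNames(rep(list(numeric()), nrow(sch)), sch$channel),
      list(his = numeric())
    ))
    return(new_his_cohort(empty,
      participants = tibble::tibble(
        participant_id = integer(), sex = character(), age = integer()
      ),
      latent = tibble::tibble(
        participant_id = integer(), day = integer(), latent = numeric()
      ),
      config = config
    ))
  }
  with_seed(config$seed, {
    sd <- config$noise_sd
    wl <- config$wellness
    days <- 0:(nd - 1)

    sex <- ifelse(stats::runif(np) < 207 / 384, "male", "female")
    age <- pmin(pmax(round(stats::rnorm(np, 37, 9)), 18L), 65L)
    height <- stats::rnorm(np, ifelse(sex == "male", 1.76, 1.64), 0.06)
    weight0 <- stats::rnorm(np, ifelse(sex == "male", 78, 65), 8)
    intercept <- stats::rnorm(np, 0, 0.4)

    base_traj <- latent_his_trajectory(days, config$trend)
    # latent fitness and AR(1) wellness, participant-major order
    f <- rep(intercept, each = nd) + rep(base_traj, times = np)
    w <- numeric(np * nd)
    innov_sd <- wl$sd * sqrt(1 - wl$rho^2)
    for (p in seq_len(np)) {
      off <- (p - 1L) * nd
      w[off + 1L] <- stats::rnorm(1, 0, wl$sd)
      for (d in 2:nd) {
        w[off + d] <- wl$rho * w[off + d - 1L] + stats::rnorm(1, 0, innov_sd)
      }
    }
    n <- np * nd
    e <- function(channel) stats::rnorm(n, 0, sd[[channel]])
    fc <- f - 5 # centred fitness

    # acute strain events: flagged by the wearables on the day itself,
    # depressing HIS on later days per the lag profile (delayed onset)
    ev <- config$events %||% list(rate = 0)
    event_day <- if ((ev$rate %||% 0) > 0) stats::runif(n) < ev$rate else rep(FALSE, n)
    his_event_effect <- numeric(n)
    if (any(event_day)) {
      for (j in seq_along(ev$lag_profile)) {
        lagged <- c(rep(FALSE, j), event_day[seq_len(n - j)])
        # do not let an event bleed across the participant boundary
        lagged[rep(seq_len(nd), times = np) <= j] <- FALSE
        his_event_effect <- his_event_effect -
          lagged * ev$his_drop * ev$lag_profile[j]
      }
    }
    evn <- as.numeric(event_day)

    steps <- pmax(7000 + 1200 * fc + 1100 * w + e("steps"), 0)
    sit_h <- pmax(9.0 - 0.5 * fc - 0.3 * w + e("sitting_frac"), 0.5)
    stand_h <- pmax(5.0 + 0.4 * fc + 0.2 * w + e("standing_frac"), 0.5)
    lie_h <- pmax(9.5 - 0.1 * fc + e("lying_frac"), 0.5)
    post_tot <- sit_h + stand_h + lie_h
    deep <- pmax(0.22 + 0.02 * fc + 0.01 * w - 0.08 * evn + e("deep_frac"), 0.05)
    light <- pmax(0.55 - 0.01 * fc + e("light_frac"), 0.05)
    rem <- pmax(0.23 + e("rem_frac"), 0.05)
    phase_tot <- deep + light + rem
    weight <- rep(weight0, each = nd) - 0.15 * fc + e("weight")

    ch <- list(
      hr_rest = 68 - 2.0 * fc - 2.0 * w + 8 * evn + e("hr_rest"),
      hr_active = 118 - 2.5 * fc - 1.5 * w + 10 * evn + e("hr_active"),
      hrv = pmax(45 + 4 * fc + 4.5 * w - 12 * evn + e("hrv"), 5),
      spo2 = pmin(pmax(96.5 + 0.3 * fc + 0.2 * w - 0.5 * evn + e("spo2"), 85), 100),
      resp_rate = pmax(15 - 0.5 * fc - 0.3 * w + 1.5 * evn + e("resp_rate"), 8),
      body_temp = 36.6 + 0.05 * w + 0.3 * evn + e("body_temp"),
      steps = steps,
      step_intensity = pmax(1 + 0.15 * fc + 0.1 * w + e("step_intensity"), 0),
      distance = pmax(steps * 0.00075 + e("distance"), 0),
      calories = pmax(2100 + 180 * fc + 120 * w + e("calories"), 800),
      active_minutes = pmax(38 + 8 * fc + 6 * w + e("active_minutes"), 0),
      sitting_frac = sit_h / post_tot,
      standing_frac = stand_h / post_tot,
      lying_frac = lie_h / post_tot,
      sleep_hours = pmin(pmax(7.2 + 0.15 * fc + 0.2 * w - 1.5 * evn + e("sleep_hours"), 3), 11),
      deep_frac = deep / phase_tot,
      light_frac = light / phase_tot,
      rem_frac = rem / phase_tot,
      interruptions = pmax(round(2 - 0.4 * fc - 0.3 * w + 3 * evn + e("interruptions")), 0),
      weight = weight,
      bmi = weight / rep(height, each = nd)^2
    )

    his <- f + wl$gain * w + his_event_effect + stats::rnorm(n, 0, sd[["his"]])
    if (config$round_his) his <- round(his)
    his <- pmin(pmax(his, 1), 10)

    cohort <- tibble::as_tibble(c(
      list(
        participant_id = rep(seq_len(np), each = nd),
        day = rep(days, times = np)
      ),
      ch[sch$channel],
      list(his = his)
    ))

    if (!is.null(config$spike_events)) {
      ev <- config$spike_events
      for (i in seq_len(nrow(ev))) {
        row <- which(cohort$participant_id == ev$participant[i] &
          cohort$day == ev$day[i])
        if (length(row) == 1L) {
          cohort[[ev$channel[i]]][row] <-
            cohort[[ev$channel[i]]][row] + ev$magnitude[i]
        }
      }
    }

    cohort <- new_his_cohort(cohort,
      participants = tibble::tibble(
        participant_id = seq_len(np), sex = sex, age = age
      ),
      latent = tibble::tibble(
        participant_id = rep(seq_len(np), each = nd),
        day = rep(days, times = np),
        latent = f,
        event = event_day
      ),
      config = config
    )
    if (config$missing_rate > 0) {
      cohort <- inject_missingness(cohort, config$missing_rate,
        seed = derive_seed(config$seed, 1L)
      )
    }
    cohort
  })
}

new_his_cohort <- function(x, participants, latent, config) {
  structure(x,
    class = c("his_cohort", class(tibble::tibble())),
    participants = participants, latent = latent, config = config
  )
}

#' Inject missingness into a cohort
#'
#' Marks approximately `missing_rate` of channel cells missing (as `NA`),
#' uniformly at random under `seed`. The HIS target is never masked.
#'
#' @param cohort A `his_cohort` tibble.
#' @param missing_rate Fraction in `[0, 1)`.
#' @param seed Integer seed for the mask.
#' @return The cohort with `NA`s planted in channel columns.
#' @export
inject_missingness <- function(cohort, missing_rate, seed = 1) {
  check_fraction(missing_rate, "missing_rate")
  if (missing_rate == 0) {
    return(cohort)
  }
  channels <- intersect(schema_channels(), names(cohort))
  with_seed(seed, {
    for (chn in channels) {
      mask <- stats::runif(nrow(cohort)) < missing_rate
      cohort[[chn]][mask] <- NA_real_
    }
  })
  cohort
}

#' Missingness mask of a cohort
#'
#' @param cohort A `his_cohort` tibble.
#' @return Logical matrix (rows = participant-days, columns = channels),
#'   `TRUE` where the cell is missing.
#' @export
cohort_mask <- function(cohort) {
  channels <- intersect(schema_channels(), names(cohort))
  m <- is.na(as.matrix(cohort[channels]))
  rownames(m) <- NULL
  m
}

#' Planted-event window fixture for attention tests
#'
#' Builds a windowed dataset in which the target is carried by a single
#' channel at one fixed position inside every window: that channel is near
#' zero except at `spike_pos`, where it takes a uniform value the target
#' copies (plus noise); remaining channels are uninformative noise. A
#' temporal-attention model trained on this fixture should concentrate
#' weight on the spike position. All values are on the normalized [0, 1]
#' scale.
#'
#' @param n_windows Number of windows.
#' @param T Window length in days.
#' @param spike_pos 1-based position of the informative day within the
#'   window.
#' @param n_channels Total channels (channel 1 is the signal channel).
#' @param noise_sd Standard deviation of target and background noise.
#' @param seed Integer seed.
#' @return A `his_windows` object (see [make_windows()]); each window is
#'   its own group, so the cross-window smoothness term is inactive.
#' @export
attention_fixture <- function(n_windows = 256, T = 7, spike_pos = 4,
                              n_channels = 4, noise_sd = 0.05, seed = 1) {
  stopifnot(spike_pos >= 1, spike_pos <= T, n_channels >= 1)
  with_seed(seed, {
    x <- array(stats::runif(n_windows * T * n_channels), c(n_windows, T, n_channels))
    signal <- stats::runif(n_windows)
    x[, , 1] <- abs(stats::rnorm(n_windows * T, 0, noise_sd))
    x[, spike_pos, 1] <- signal
    y <- matrix(pmin(pmax(signal + stats::rnorm(n_windows, 0, noise_sd), 0), 1),
      ncol = 1
    )
    new_his_windows(
      x = x, y = y,
      index = tibble::tibble(
        participant_id = seq_len(n_windows), start_day = 0L
      ),
      channels = paste0("ch", seq_len(n_channels)),
      T = T, H = 1L, stride = 1L,
      his_lags = matrix(0, n_windows, T)
    )
  })
}

#' Write / read a cohort as tidy CSV
#'
#' `write_cohort()` writes `channels.csv` (long format: `participant_id,
#' day, channel, value, missing`) and `his.csv` (`participant_id, day,
#' his`) into `dir`; `read_cohort()` reconstructs the wide cohort tibble.
#'
#' @param cohort A `his_cohort` tibble.
#' @param dir Output directory (created if absent).
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()`
#'   returns a `his_cohort` tibble (without simulator attributes).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  channels <- intersect(schema_channels(), names(cohort))
  long <- tidyr::pivot_longer(
    tibble::as_tibble(cohort)[c("participant_id", "day", channels)],
    cols = dplyr::all_of(channels),
    names_to = "channel", values_to = "value"
  )
  long$missing <- is.na(long$value)
  readr::write_csv(long, file.path(dir, "channels.csv"))
  readr::write_csv(
    tibble::as_tibble(cohort)[c("participant_id", "day", "his")],
    file.path(dir, "his.csv")
  )
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  long <- readr::read_csv(file.path(dir, "channels.csv"),
    show_col_types = FALSE
  )
  his <- readr::read_csv(file.path(dir, "his.csv"), show_col_types = FALSE)
  wide <- tidyr::pivot_wider(long[c("participant_id", "day", "channel", "value")],
    names_from = "channel", values_from = "value"
  )
  out <- dplyr::arrange(
    dplyr::left_join(wide, his, by = c("participant_id", "day")),
    .data$participant_id, .data$day
  )
  keep <- c("participant_id", "day", intersect(schema_channels(), names(out)), "his")
  structure(out[keep], class = c("his_cohort", class(tibble::tibble())))
}

#' Plot a cohort's HIS trend
#'
#' Mean observed HIS per day with an interquartile ribbon, plus the latent
#' population trajectory when the cohort carries it.
#'
#' @param object A `his_cohort` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.his_cohort <- function(object, ...) {
  daily <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(object), .data$day),
    mean_his = mean(.data$his),
    lo = stats::quantile(.data$his, 0.25),
    hi = stats::quantile(.data$his, 0.75),
    .groups = "drop"
  )
  p <- ggplot2::ggplot(daily, ggplot2::aes(x = .data$day, y = .data$mean_his)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
      fill = "steelblue", alpha = 0.25
    ) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "Day", y = "HIS", title = "Cohort HIS trend")
  latent <- attr(object, "latent")
  if (!is.null(latent)) {
    lat <- dplyr::summarise(
      dplyr::group_by(latent, .data$day),
      latent = mean(.data$latent), .groups = "drop"
    )
    p <- p + ggplot2::geom_line(
      data = lat, ggplot2::aes(y = .data$latent),
      linetype = "dashed", colour = "grey30"
    )
  }
  p
}
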