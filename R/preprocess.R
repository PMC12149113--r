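#' Exclude participants with sparse records
#'
#' Drops every participant whose fraction of missing channel cells over the
#' whole observation period strictly exceeds `threshold` (a record with
#' exactly the threshold fraction is kept).
#'
#' @param cohort A `his_cohort` tibble with `NA`s marking missing cells.
#' @param threshold Missingness fraction above which a participant is
#'   removed; default 0.2.
#' @return The retained cohort, with attribute `excluded`: a tibble
#'   (`participant_id`, `missing_frac`) of removed participants.
#' @export
exclude_sparse_participants <- function(cohort, threshold = 0.2) {
  check_fraction(threshold, "threshold", allow_one = TRUE)
  channels <- intersect(schema_channels(), names(cohort))
  frac <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(cohort), .data$participant_id),
    missing_frac = mean(is.na(as.matrix(dplyr::pick(dplyr::all_of(channels))))),
    .groups = "drop"
  )
  dropped <- dplyr::filter(frac, .data$missing_frac > threshold)
  kept <- cohort[!cohort$participant_id %in% dropped$participant_id, ]
  attr(kept, "excluded") <- dropped
  for (a in c("participants", "latent", "config")) {
    attr(kept, a) <- attr(cohort, a)
  }
  kept
}

#' Forward-fill missing channel values
#'
#' Imputes each participant's channels independently: a missing cell takes
#' the most recent prior observed value; leading missing cells (no prior
#' observation) take the channel's first observed value. A channel with no
#' observation at all for some participant is an error naming both.
#'
#' @param cohort A `his_cohort` tibble.
#' @return The cohort with all channel `NA`s filled.
#' @export
forward_fill <- function(cohort) {
  channels <- intersect(schema_channels(), names(cohort))
  out <- dplyr::group_by(tibble::as_tibble(cohort), .data$participant_id)
  out <- dplyr::arrange(out, .data$day, .by_group = TRUE)
  out <- dplyr::mutate(out, dplyr::across(
    dplyr::all_of(channels),
    function(v) {
      if (all(is.na(v))) {
        stop(
          "participant ", dplyr::cur_group()$participant_id,
          ": channel '", dplyr::cur_column(), "' has no observed values",
          call. = FALSE
        )
      }
      zoo::na.locf(zoo::na.locf(v, na.rm = FALSE), fromLast = TRUE)
    }
  ))
  out <- dplyr::ungroup(out)
  for (a in c("participants", "latent", "config", "excluded")) {
    attr(out, a) <- attr(cohort, a)
  }
  class(out) <- c("his_cohort", class(tibble::tibble()))
  out
}

#' Min-max normalize cohort channels to [0, 1]
#'
#' Per channel, maps `x` to `(x - min) / (max - min)`. When `scalers` is
#' `NULL` the extrema are computed from the supplied data (pass the
#' training split only, to avoid leakage into validation/test); when
#' supplied, they are applied unchanged and the result is clipped to
#' [0, 1]. A constant channel maps to 0. The HIS column is left on its
#' 1-10 scale; see [normalize_his()].
#'
#' @param cohort A `his_cohort` tibble with no missing channel values.
#' @param scalers Optional tibble (`channel`, `min`, `max`) from a previous
#'   call.
#' @return List with `cohort` (scaled) and `scalers`.
#' @export
minmax_normalize <- function(cohort, scalers = NULL) {
  channels <- intersect(schema_channels(), names(cohort))
  if (anyNA(cohort[channels])) {
    stop("cohort still contains missing channel values; forward_fill() first",
      call. = FALSE
    )
  }
  if (is.null(scalers)) {
    scalers <- tibble::tibble(
      channel = channels,
      min = vapply(cohort[channels], min, numeric(1)),
      max = vapply(cohort[channels], max, numeric(1))
    )
    clip <- FALSE
  } else {
    missing_ch <- setdiff(channels, scalers$channel)
    if (length(missing_ch) > 0) {
      stop("scalers lack channels: ", paste(missing_ch, collapse = ", "),
        call. = FALSE
      )
    }
    bad <- vapply(channels, function(chn) {
      s <- scalers[scalers$channel == chn, ]
      s$min == s$max && stats::var(cohort[[chn]]) > 0
    }, logical(1))
    if (any(bad)) {
      stop(
        "scalers have min = max for non-constant channel(s): ",
        paste(channels[bad], collapse = ", "),
        call. = FALSE
      )
    }
    clip <- TRUE
  }
  out <- cohort
  for (chn in channels) {
    s <- scalers[scalers$channel == chn, ]
    rng <- s$max - s$min
    v <- if (rng == 0) rep(0, nrow(out)) else (out[[chn]] - s$min) / rng
    if (clip) v <- pmin(pmax(v, 0), 1)
    out[[chn]] <- v
  }
  list(cohort = out, scalers = scalers)
}

#' Invert min-max scaling for one channel
#'
#' @param x Normalized values.
#' @param channel Channel name.
#' @param scalers Scaler tibble from [minmax_normalize()].
#' @return Values on the original scale.
#' @export
minmax_denormalize <- function(x, channel, scalers) {
  s <- scalers[scalers$channel == channel, ]
  if (nrow(s) != 1L) stop("unknown channel '", channel, "'", call. = FALSE)
  x * (s$max - s$min) + s$min
}

#' HIS target scaling
#'
#' The 1-10 HIS target is trained on the fixed affine scale
#' `(his - 1) / 9` in `[0, 1]`; all reported metrics are computed after
#' inverting back to the 1-10 scale.
#'
#' @param his HIS values (1-10 scale) or normalized values.
#' @return Scaled (`normalize_his`) or unscaled (`denormalize_his`) values.
#' @export
normalize_his <- function(his) (his - 1) / 9

#' @rdname normalize_his
#' @export
denormalize_his <- function(his) his * 9 + 1

new_his_windows <- function(x, y, index, channels, T, H, stride, his_lags) {
  structure(
    list(
      x = x, y = y, index = index, channels = channels,
      T = as.integer(T), H = as.integer(H), stride = as.integer(stride),
      his_lags = his_lags
    ),
    class = "his_windows"
  )
}

#' @export
print.his_windows <- function(x, ...) {
  cat(
    "<his_windows> ", dim(x$x)[1], " windows (T = ", x$T, ", H = ", x$H,
    ", stride = ", x$stride, ", ", length(x$channels), " channels, ",
    dplyr::n_distinct(x$index$participant_id), " participants)\n",
    sep = ""
  )
  invisible(x)
}

#' @export
dim.his_windows <- function(x) dim(x$x)

#' Segment a cohort into overlapping windows
#'
#' For each participant, emits input windows covering days
#' `[s, s + T - 1]` for `s = 0, stride, 2 stride, ...` with target HIS on
#' days `[s + T, s + T + H - 1]`; windows never cross participants. Input
#' channels must already be normalized; targets are stored on the
#' normalized `(his - 1) / 9` scale. Each window also records the HIS
#' values of its own days (for persistence/autoregressive baselines).
#'
#' @param cohort A normalized, fully imputed `his_cohort` tibble.
#' @param T Window length in days (default 7).
#' @param stride Step between consecutive window starts (default 1).
#' @param H Forecast horizon in days (default 1).
#' @param include_his If `TRUE`, the (normalized) HIS of each window day
#'   is appended as an extra input channel `his_lag`, enabling
#'   autoregressive-HIS modelling; default `FALSE` keeps HIS a target
#'   only.
#' @return A `his_windows` object: `x` array `(n, T, channels)`, `y` matrix
#'   `(n, H)`, `index` tibble (`participant_id`, `start_day`), `his_lags`
#'   matrix `(n, T)`.
#' @examples
#' # 32 days, T = 7, H = 1, stride = 1 -> 25 windows per participant
#' @export
make_windows <- function(cohort, T = 7, stride = 1, H = 1,
                         include_his = FALSE) {
  T <- check_count(T, "T", min = 1L)
  H <- check_count(H, "H", min = 1L)
  stride <- check_count(stride, "stride", min = 1L)
  channels <- intersect(schema_channels(), names(cohort))
  if (anyNA(cohort[channels])) {
    stop("cohort contains missing values; forward_fill() first", call. = FALSE)
  }
  df <- dplyr::arrange(
    tibble::as_tibble(cohort), .data$participant_id, .data$day
  )
  pieces_x <- list()
  pieces_y <- list()
  pieces_lag <- list()
  idx_pid <- integer()
  idx_start <- integer()
  for (pid in unique(df$participant_id)) {
    sub <- df[df$participant_id == pid, ]
    nd <- nrow(sub)
    if (nd < T + H) {
      warning("participant ", pid, ": ", nd, " days < T + H = ", T + H,
        "; no windows emitted",
        call. = FALSE
      )
      next
    }
    starts <- seq(0L, nd - T - H, by = stride)
    mat <- as.matrix(sub[channels])
    his_n <- normalize_his(sub$his)
    if (include_his) mat <- cbind(mat, his_lag = his_n)
    for (s in starts) {
      pieces_x[[length(pieces_x) + 1L]] <- mat[(s + 1):(s + T), , drop = FALSE]
      pieces_y[[length(pieces_y) + 1L]] <- his_n[(s + T + 1):(s + T + H)]
      pieces_lag[[length(pieces_lag) + 1L]] <- his_n[(s + 1):(s + T)]
      idx_pid <- c(idx_pid, pid)
      idx_start <- c(idx_start, s)
    }
  }
  n <- length(pieces_x)
  if (include_his) channels <- c(channels, "his_lag")
  x <- array(0, c(n, T, length(channels)), dimnames = list(NULL, NULL, channels))
  y <- matrix(0, n, H)
  lags <- matrix(0, n, T)
  for (i in seq_len(n)) {
    x[i, , ] <- pieces_x[[i]]
    y[i, ] <- pieces_y[[i]]
    lags[i, ] <- pieces_lag[[i]]
  }
  new_his_windows(
    x = x, y = y,
    index = tibble::tibble(participant_id = idx_pid, start_day = idx_start),
    channels = channels, T = T, H = H, stride = stride, his_lags = lags
  )
}

subset_windows <- function(windows, i) {
  new_his_windows(
    x = windows$x[i, , , drop = FALSE],
    y = windows$y[i, , drop = FALSE],
    index = windows$index[i, ],
    channels = windows$channels, T = windows$T, H = windows$H,
    stride = windows$stride,
    his_lags = windows$his_lags[i, , drop = FALSE]
  )
}

#' Split participants into train/validation/test sets
#'
#' Participant-level (never window-level) random partition, so overlapping
#' windows of one person cannot straddle splits. Validation and test sizes
#' are `floor(fraction * n)`; the remainder goes to training.
#'
#' @param ids Vector of participant ids.
#' @param fractions Length-3 numeric (train, val, test) summing to 1.
#' @param seed Integer seed; the partition is deterministic in it.
#' @return List of class `split_spec` with `train`, `val`, `test` id
#'   vectors and the seed.
#' @export
split_participants <- function(ids, fractions = c(0.70, 0.15, 0.15), seed = 1) {
  ids <- unique(ids)
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-8) {
    stop("`fractions` must be three numbers summing to 1", call. = FALSE)
  }
  n_groups <- sum(fractions > 0)
  if (length(ids) < n_groups) {
    stop(
      "need at least ", n_groups, " participants for ", n_groups,
      " non-empty splits, got ", length(ids),
      call. = FALSE
    )
  }
  with_seed(seed, {
    shuffled <- sample(ids)
    n <- length(ids)
    n_val <- floor(fractions[2] * n)
    n_test <- floor(fractions[3] * n)
    test <- if (n_test > 0) shuffled[seq_len(n_test)] else ids[0]
    val <- if (n_val > 0) shuffled[n_test + seq_len(n_val)] else ids[0]
    train <- if (n_test + n_val > 0) {
      shuffled[-seq_len(n_test + n_val)]
    } else {
      shuffled
    }
    if (length(train) == 0 && fractions[1] > 0) {
      stop("training split is empty", call. = FALSE)
    }
    structure(
      list(train = sort(train), val = sort(val), test = sort(test), seed = seed),
      class = "split_spec"
    )
  })
}

#' Run the full preprocessing pipeline
#'
#' Exclusion (> `threshold` missing), forward-fill, participant split,
#' min-max normalization fit on the training split only, and windowing —
#' in the order the modelling stage expects.
#'
#' @param cohort A raw `his_cohort` tibble (may contain `NA`s).
#' @param T,stride,H Windowing parameters, see [make_windows()].
#' @param fractions,seed Split parameters, see [split_participants()].
#' @param threshold Exclusion threshold, see
#'   [exclude_sparse_participants()].
#' @param include_his Append HIS as an input channel, see
#'   [make_windows()].
#' @return List with `train`, `val`, `test` (`his_windows`; `val`/`test`
#'   `NULL` when their fraction is 0), `scalers`, `split`, and
#'   `excluded`.
#' @export
prepare_datasets <- function(cohort, T = 7, stride = 1, H = 1,
                             fractions = c(0.70, 0.15, 0.15), seed = 1,
                             threshold = 0.2, include_his = FALSE) {
  kept <- exclude_sparse_participants(cohort, threshold)
  excluded <- attr(kept, "excluded")
  filled <- forward_fill(kept)
  split <- split_participants(unique(filled$participant_id), fractions, seed)
  train_raw <- filled[filled$participant_id %in% split$train, ]
  norm_train <- minmax_normalize(train_raw)
  scalers <- norm_train$scalers
  window_split <- function(ids) {
    if (length(ids) == 0) {
      return(NULL)
    }
    part <- filled[filled$participant_id %in% ids, ]
    make_windows(
      minmax_normalize(part, scalers)$cohort, T, stride, H, include_his
    )
  }
  list(
    train = make_windows(norm_train$cohort, T, stride, H, include_his),
    val = window_split(split$val),
    test = window_split(split$test),
    scalers = scalers, split = split, excluded = excluded
  )
}
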