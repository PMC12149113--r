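# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so simulation functions are pure in their `seed` argument.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        suppressWarnings(rm(".Random.seed", envir = globalenv()))
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Derive a per-stage sub-seed from one root seed so pipeline stages are
# independently reproducible. Kept below 2^31 - 1.
derive_seed <- function(seed, stage) {
  offsets <- c(
    simulate = 1L, preprocess = 2L, train = 3L, tune = 4L,
    evaluate = 5L, forecast = 6L
  )
  if (is.character(stage)) {
    if (!stage %in% names(offsets)) {
      stop("unknown stage '", stage, "'", call. = FALSE)
    }
    stage <- offsets[[stage]]
  }
  (as.integer(seed) %% 1000003L) * 2011L + as.integer(stage) * 7919L
}

check_fraction <- function(x, name, allow_one = FALSE) {
  hi_ok <- if (allow_one) x <= 1 else x < 1
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || !hi_ok) {
    stop("`", name, "` must be a fraction in [0, 1", if (allow_one) "]" else ")",
      call. = FALSE
    )
  }
  invisible(x)
}

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
    x != as.integer(x)) {
    stop("`", name, "` must be an integer >= ", min, call. = FALSE)
  }
  invisible(as.integer(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
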