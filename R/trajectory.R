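#' Latent HIS trend parameters
#'
#' Parameters of the population-level latent health trajectory the cohort
#' simulator builds HIS values around: an initial improvement phase, a
#' transient dip (the adaptation slump wearable studies commonly report),
#' then a resumed climb whose day-to-day gains shrink as fitness saturates.
#'
#' @param base Trajectory value at day 0, in HIS units (1-10 scale).
#' @param initial_gain_rate Daily HIS gain during the initial phase
#'   (HIS units / day).
#' @param dip_day 0-based day index at which the dip bottoms out.
#' @param dip_depth Size of the dip in HIS units (>= 0).
#' @param recovery_rate Initial post-dip daily gain (HIS units / day).
#' @param plateau_strength Saturation rate of the recovery (1/day, >= 0);
#'   0 keeps the recovery linear, larger values shrink successive gains
#'   faster.
#' @return A named list of trend parameters.
#' @export
trend_params <- function(base = 5, initial_gain_rate = 0.12, dip_day = 14,
                         dip_depth = 0.5, recovery_rate = 0.12,
                         plateau_strength = 0.08) {
  stopifnot(dip_day >= 1, dip_depth >= 0, plateau_strength >= 0)
  list(
    base = base, initial_gain_rate = initial_gain_rate, dip_day = dip_day,
    dip_depth = dip_depth, recovery_rate = recovery_rate,
    plateau_strength = plateau_strength
  )
}

#' Latent HIS trajectory
#'
#' Piecewise latent trajectory in HIS units: a linear rise up to
#' `dip_day - 1`, a linear descent of `dip_depth` over the following day,
#' then a saturating recovery `r (1 - exp(-p u)) / p` (`u` days past the
#' dip, `r = recovery_rate`, `p = plateau_strength`) whose increments are
#' strictly decreasing for `p > 0`. Continuous in `day`, which may be
#' fractional.
#'
#' @param day Numeric vector of 0-based day indices (may be fractional).
#' @param trend A list from [trend_params()].
#' @param n_days Optional upper bound; days outside `[0, n_days)` are
#'   rejected.
#' @return Numeric vector of latent HIS values, same length as `day`.
#' @examples
#' latent_his_trajectory(0:31, trend_params())
#' @export
latent_his_trajectory <- function(day, trend = trend_params(), n_days = NULL) {
  if (any(day < 0)) stop("`day` must be >= 0", call. = FALSE)
  if (!is.null(n_days) && any(day >= n_days)) {
    stop("`day` must be < n_days (", n_days, ")", call. = FALSE)
  }
  rise <- trend$initial_gain_rate * pmin(day, trend$dip_day - 1)
  dip <- -trend$dip_depth * pmin(pmax(day - (trend$dip_day - 1), 0), 1)
  u <- pmax(day - trend$dip_day, 0)
  rec <- if (trend$plateau_strength > 0) {
    trend$recovery_rate *
      (1 - exp(-trend$plateau_strength * u)) / trend$plateau_strength
  } else {
    trend$recovery_rate * u
  }
  trend$base + rise + dip + rec
}
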