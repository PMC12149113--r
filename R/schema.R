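#' Wearable feature schema
#'
#' The ordered set of daily channels a cohort record carries, grouped into
#' the four domains a multi-sensor wearable platform reports: physiological
#' (heart rate, oxygen saturation, respiration, temperature), activity
#' (steps, distance, energy, posture), sleep (duration, phase fractions,
#' interruptions) and body (weight, BMI). Every cohort column outside
#' `participant_id`, `day` and `his` maps to exactly one schema entry.
#'
#' @return A tibble with columns `channel` (unique name) and `domain`
#'   (one of `"physiological"`, `"activity"`, `"sleep"`, `"body"`).
#' @examples
#' feature_schema()
#' @export
feature_schema <- function() {
  tibble::tibble(
    channel = c(
      "hr_rest", "hr_active", "hrv", "spo2", "resp_rate", "body_temp",
      "steps", "step_intensity", "distance", "calories", "active_minutes",
      "sitting_frac", "standing_frac", "lying_frac",
      "sleep_hours", "deep_frac", "light_frac", "rem_frac", "interruptions",
      "weight", "bmi"
    ),
    domain = c(
      rep("physiological", 6L),
      rep("activity", 8L),
      rep("sleep", 5L),
      rep("body", 2L)
    )
  )
}

#' @rdname feature_schema
#' @export
schema_channels <- function() feature_schema()$channel
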