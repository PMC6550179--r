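#' Gait profile for the walking-signal simulator
#'
#' A `gait_profile` bundles the generative parameters for one walking
#' archetype: cadence and its between-subject spread, within-subject
#' step-timing variability, the static (gravity-dominated) acceleration
#' baseline of each axis, the amplitudes of the periodic movement
#' components, sensor noise, and the schedule of turns and pauses of a
#' 400-m hallway walk (cones 20 m apart, 180-degree turns at each cone).
#'
#' Axis convention for a right-hip-worn device: `x` anteroposterior,
#' `y` vertical (gravity makes its baseline negative), `z` mediolateral.
#'
#' @param cadence_mean Mean cadence, steps/min. Must be positive.
#' @param cadence_sd_between_subjects Between-subject SD of cadence,
#'   steps/min.
#' @param step_time_cv_within Within-subject coefficient of variation of
#'   step time (unitless, < 1). Step intervals are drawn i.i.d. normal.
#' @param vertical_baseline,ap_baseline,ml_baseline Static acceleration of
#'   the y/x/z axis in g (gravity projection on the tilted device).
#' @param vertical_impulse_amp Amplitude of the per-step raised-cosine
#'   impulse on the vertical axis, g.
#' @param ap_sway_amp Amplitude of anteroposterior oscillation at step
#'   frequency, g.
#' @param ml_sway_amp Mean amplitude of mediolateral oscillation at stride
#'   frequency (half the step frequency), g.
#' @param ml_sway_amp_cv Coefficient of variation of the per-stride
#'   mediolateral amplitude (stride-to-stride sway variability).
#' @param noise_sd White sensor-noise SD per axis, g.
#' @param turn_every_m Distance between turns, m (cone spacing).
#' @param turn_duration_s Duration of the turn disturbance, s.
#' @param pause_prob_per_lap Probability of one spontaneous pause per lap
#'   (a lap is out-and-back, `2 * turn_every_m` metres).
#' @param pause_duration_s Duration of a pause, s.
#' @param step_length_m Assumed step length used to convert cadence into
#'   walking speed for the turn/pause schedule, m.
#'
#' @return An object of class `gait_profile` (a validated named list).
#' @export
gait_profile <- function(cadence_mean = 123.5,
                         cadence_sd_between_subjects = 16.5,
                         step_time_cv_within = 0.04,
                         vertical_baseline = -0.889,
                         ap_baseline = -0.137,
                         ml_baseline = -0.124,
                         vertical_impulse_amp = 0.50,
                         ap_sway_amp = 0.15,
                         ml_sway_amp = 0.12,
                         ml_sway_amp_cv = 0.45,
                         noise_sd = 0.03,
                         turn_every_m = 20,
                         turn_duration_s = 2.5,
                         pause_prob_per_lap = 0.2,
                         pause_duration_s = 2.5,
                         step_length_m = 0.6) {
  p <- list(
    cadence_mean = cadence_mean,
    cadence_sd_between_subjects = cadence_sd_between_subjects,
    step_time_cv_within = step_time_cv_within,
    vertical_baseline = vertical_baseline,
    ap_baseline = ap_baseline,
    ml_baseline = ml_baseline,
    vertical_impulse_amp = vertical_impulse_amp,
    ap_sway_amp = ap_sway_amp,
    ml_sway_amp = ml_sway_amp,
    ml_sway_amp_cv = ml_sway_amp_cv,
    noise_sd = noise_sd,
    turn_every_m = turn_every_m,
    turn_duration_s = turn_duration_s,
    pause_prob_per_lap = pause_prob_per_lap,
    pause_duration_s = pause_duration_s,
    step_length_m = step_length_m
  )
  validate_gait_profile(p)
  structure(p, class = "gait_profile")
}

validate_gait_profile <- function(p) {
  if (p$cadence_mean <= 0) stop_input("cadence_mean must be > 0")
  nonneg <- c(
    "cadence_sd_between_subjects", "step_time_cv_within",
    "vertical_impulse_amp", "ap_sway_amp", "ml_sway_amp",
    "ml_sway_amp_cv", "noise_sd", "turn_duration_s", "pause_duration_s",
    "step_length_m"
  )
  for (f in nonneg) {
    if (p[[f]] < 0) stop_input("%s must be >= 0", f)
  }
  if (p$step_time_cv_within >= 1) stop_input("step_time_cv_within must be < 1")
  if (p$pause_prob_per_lap < 0 || p$pause_prob_per_lap > 1) {
    stop_input("pause_prob_per_lap must be in [0, 1]")
  }
  invisible(p)
}

#' High- and low-fall-risk walking archetypes
#'
#' Returns the pair of default [gait_profile()]s used throughout the
#' package. The defaults encode the group contrasts of the calibration
#' cohort that motivates the simulator: the high-risk archetype walks with
#' lower cadence (120.5 vs 124.6 steps/min), carries a more negative mean
#' vertical acceleration (-0.910 vs -0.881 g), has more variable step
#' timing, and shows larger stride-to-stride mediolateral sway
#' variability (`ml_sway_amp_cv` 1.5 times the low-risk value).
#'
#' @param overrides Named list of overrides. Names are
#'   `"high.<field>"`, `"low.<field>"`, or `"<field>"` (applied to both
#'   archetypes), where `<field>` is a [gait_profile()] argument.
#'   Unknown names are an error.
#'
#' @return A list with elements `high` and `low`, each a `gait_profile`.
#' @examples
#' arch <- make_archetypes()
#' arch$high$cadence_mean  # 120.5
#' arch <- make_archetypes(list("low.cadence_mean" = 120.5))
#' @export
make_archetypes <- function(overrides = list()) {
  high <- list(
    cadence_mean = 120.5,
    cadence_sd_between_subjects = 15.5,
    step_time_cv_within = 0.05,
    vertical_baseline = -0.910,
    ap_baseline = -0.103,
    ml_baseline = -0.044,
    vertical_impulse_amp = 0.48,
    ap_sway_amp = 0.15,
    ml_sway_amp = 0.12,
    ml_sway_amp_cv = 0.60,
    noise_sd = 0.03,
    turn_every_m = 20,
    turn_duration_s = 2.5,
    pause_prob_per_lap = 0.25,
    pause_duration_s = 2.5,
    step_length_m = 0.6
  )
  low <- list(
    cadence_mean = 124.6,
    cadence_sd_between_subjects = 16.7,
    step_time_cv_within = 0.03,
    vertical_baseline = -0.881,
    ap_baseline = -0.149,
    ml_baseline = -0.153,
    vertical_impulse_amp = 0.52,
    ap_sway_amp = 0.15,
    ml_sway_amp = 0.12,
    ml_sway_amp_cv = 0.40,
    noise_sd = 0.03,
    turn_every_m = 20,
    turn_duration_s = 2.5,
    pause_prob_per_lap = 0.15,
    pause_duration_s = 2.5,
    step_length_m = 0.6
  )
  known <- names(high)
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(names(overrides) == "")) {
      stop_input("all overrides must be named")
    }
    for (key in names(overrides)) {
      parts <- strsplit(key, ".", fixed = TRUE)[[1]]
      if (length(parts) == 1L) {
        grp <- "both"
        field <- parts[1]
      } else if (length(parts) == 2L && parts[1] %in% c("high", "low")) {
        grp <- parts[1]
        field <- parts[2]
      } else {
        stop_input("unknown override key: '%s'", key)
      }
      if (!field %in% known) {
        stop_input("unknown override key: '%s' (no field '%s')", key, field)
      }
      val <- overrides[[key]]
      if (grp %in% c("high", "both")) high[[field]] <- val
      if (grp %in% c("low", "both")) low[[field]] <- val
    }
  }
  list(
    high = do.call(gait_profile, high),
    low = do.call(gait_profile, low)
  )
}

#' Cohort specification for the simulator
#'
#' @param n_high,n_low Number of high- and low-fall-risk subjects.
#' @param duration_s Tracing duration per subject, s. The default, 320 s,
#'   is roughly a 400-m walk at the archetypes' walking speed.
#' @param rate_hz Sampling rate, Hz.
#' @param seed Master seed; every random draw in the cohort derives from
#'   it (per-subject streams use `seed + subject index`).
#' @param high_profile,low_profile [gait_profile()]s for the two groups;
#'   defaults are [make_archetypes()].
#'
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_high = 19, n_low = 48, duration_s = 320,
                        rate_hz = 30, seed = 1,
                        high_profile = NULL, low_profile = NULL) {
  arch <- make_archetypes()
  spec <- list(
    n_high = n_high, n_low = n_low,
    duration_s = duration_s, rate_hz = rate_hz, seed = seed,
    high_profile = high_profile %||% arch$high,
    low_profile = low_profile %||% arch$low
  )
  if (spec$n_high < 0 || spec$n_low < 0) stop_input("n_high, n_low must be >= 0")
  if (spec$rate_hz <= 0) stop_input("rate_hz must be > 0")
  if (spec$duration_s <= 10) stop_input("duration_s must be > 10 s")
  stopifnot(inherits(spec$high_profile, "gait_profile"),
            inherits(spec$low_profile, "gait_profile"))
  structure(spec, class = "cohort_spec")
}
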