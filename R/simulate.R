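#' Simulate one subject's hip-accelerometer walking tracing
#'
#' Generates a 30 Hz (by default) triaxial acceleration series for a
#' subject walking a hallway course with 180-degree turns every
#' `turn_every_m` metres and occasional spontaneous pauses. The signal is
#' the sum of (a) a constant per-axis gravity baseline, (b) a
#' raised-cosine impulse on the vertical axis at every step, (c) a
#' sinusoidal anteroposterior component at step frequency, (d) a
#' sinusoidal mediolateral component at stride frequency whose amplitude
#' is redrawn every stride, and (e) white Gaussian sensor noise. During
#' turns the periodic components are replaced by low-pass "wander" of
#' reduced magnitude (phase-disrupted, aperiodic motion); during pauses
#' all movement components are gated off. The oscillatory sum is
#' re-centred so that each axis's tracing mean equals its baseline.
#'
#' @param profile A [gait_profile()]. `cadence_mean` is taken as this
#'   subject's cadence (between-subject draws happen in
#'   [simulate_cohort()]).
#' @param duration_s Tracing duration, s (>= 30).
#' @param rate_hz Sampling rate, Hz.
#' @param seed Integer seed; fixed seed gives a bit-identical tracing.
#' @param subject_id Identifier stored in the outputs.
#' @param label Optional risk label recorded in the ground truth.
#'
#' @return A list with elements `tracing` (class `raw_tracing`: subject
#'   id, rate, and a data frame `sample_index, ax_g, ay_g, az_g`) and
#'   `truth` (class `ground_truth`: the realized cadence, step-time SD,
#'   mediolateral sway amplitude, step times, turn and pause schedules).
#' @export
simulate_subject <- function(profile, duration_s, rate_hz = 30, seed = 1,
                             subject_id = "S001", label = NA_character_) {
  stopifnot(inherits(profile, "gait_profile"))
  if (duration_s < 30) stop_input("duration_s must be >= 30 s")
  if (rate_hz <= 0) stop_input("rate_hz must be > 0")

  with_seed(seed, {
    n <- round(duration_s * rate_hz)
    t <- (seq_len(n) - 1) / rate_hz
    tau_mean <- 60 / profile$cadence_mean
    speed <- profile$cadence_mean / 60 * profile$step_length_m

    # turn schedule: nominal progress at the profile's walking speed
    turn_starts <- numeric(0)
    if (profile$turn_every_m > 0 && profile$turn_duration_s > 0) {
      k <- seq_len(max(0, floor(duration_s * speed / profile$turn_every_m)))
      turn_starts <- k * profile$turn_every_m / speed
      turn_starts <- turn_starts[turn_starts < duration_s - 1]
    }

    # pause schedule: at most one pause per out-and-back lap
    pause_starts <- numeric(0)
    if (profile$pause_prob_per_lap > 0 && profile$pause_duration_s > 0) {
      lap_s <- 2 * profile$turn_every_m / speed
      if (profile$turn_every_m <= 0) lap_s <- 40 / speed
      bounds <- seq(0, duration_s, by = lap_s)
      for (j in seq_len(length(bounds) - 1)) {
        if (stats::runif(1) < profile$pause_prob_per_lap) {
          ps <- stats::runif(1, bounds[j], bounds[j + 1] - 0.5)
          if (ps + profile$pause_duration_s < duration_s) {
            pause_starts <- c(pause_starts, ps)
          }
        }
      }
    }
    pause_ends <- pause_starts + profile$pause_duration_s

    # step times: i.i.d. normal intervals; clock jumps over pauses
    step_times <- numeric(0)
    tcur <- 0.3
    repeat {
      inpause <- which(tcur >= pause_starts & tcur < pause_ends)
      if (length(inpause)) tcur <- pause_ends[inpause[1]]
      if (tcur > duration_s) break
      step_times <- c(step_times, tcur)
      tau <- if (profile$step_time_cv_within > 0) {
        stats::rnorm(1, tau_mean, profile$step_time_cv_within * tau_mean)
      } else {
        tau_mean
      }
      tcur <- tcur + max(tau, 0.25 * tau_mean)
    }
    n_steps <- length(step_times)

    # gait phase: 2*pi per step, piecewise linear through the step times
    phase <- if (n_steps >= 2) {
      stats::approx(step_times, 2 * pi * (seq_len(n_steps) - 1),
                    xout = t, rule = 2)$y
    } else {
      rep(0, n)
    }

    # vertical raised-cosine impulse per step
    w_imp <- 0.35 * tau_mean
    osc_y <- numeric(n)
    if (n_steps >= 1 && profile$vertical_impulse_amp > 0) {
      idx <- findInterval(t, step_times)
      dt <- t - c(-Inf, step_times)[idx + 1]
      active <- idx >= 1 & dt < w_imp
      osc_y[active] <- profile$vertical_impulse_amp * 0.5 *
        (1 - cos(2 * pi * dt[active] / w_imp))
    }

    # anteroposterior sway at step frequency
    osc_x <- profile$ap_sway_amp * sin(phase + 0.7)

    # mediolateral sway at stride frequency, amplitude redrawn per stride
    osc_z <- numeric(n)
    if (n_steps >= 2 && profile$ml_sway_amp > 0) {
      stride_starts <- step_times[seq(1, n_steps, by = 2)]
      n_strides <- length(stride_starts)
      amp <- pmax(stats::rnorm(n_strides, profile$ml_sway_amp,
                               profile$ml_sway_amp_cv * profile$ml_sway_amp),
                  0)
      sid <- pmax(findInterval(t, stride_starts), 1L)
      osc_z <- amp[sid] * sin(phase / 2 + 1.3)
    }

    # aperiodic low-pass wander substituted during turns
    turn_gate <- smooth_gate(t, turn_starts,
                             turn_starts + profile$turn_duration_s)
    if (length(turn_starts)) {
      wander <- lowpass_noise(n, rate_hz, cutoff_hz = 0.8)
      tw <- function(osc) {
        s <- sd_pop(osc)
        if (s == 0) numeric(n) else 0.3 * s * wander / sd_pop(wander)
      }
      turn_x <- tw(osc_x); turn_y <- tw(osc_y); turn_z <- tw(osc_z)
      # independent wander per axis so no cross-axis coherence survives
      if (sd_pop(osc_y) > 0) {
        turn_y <- 0.3 * sd_pop(osc_y) * {
          w2 <- lowpass_noise(n, rate_hz, 0.8); w2 / sd_pop(w2)
        }
      }
      if (sd_pop(osc_z) > 0) {
        turn_z <- 0.3 * sd_pop(osc_z) * {
          w3 <- lowpass_noise(n, rate_hz, 0.8); w3 / sd_pop(w3)
        }
      }
      osc_x <- turn_gate * osc_x + (1 - turn_gate) * turn_x
      osc_y <- turn_gate * osc_y + (1 - turn_gate) * turn_y
      osc_z <- turn_gate * osc_z + (1 - turn_gate) * turn_z
    }

    # pauses gate all movement off
    pause_gate <- smooth_gate(t, pause_starts, pause_ends)
    osc_x <- osc_x * pause_gate
    osc_y <- osc_y * pause_gate
    osc_z <- osc_z * pause_gate

    # re-centre so each axis mean equals its gravity baseline exactly
    if (any(osc_x != 0)) osc_x <- osc_x - mean(osc_x)
    if (any(osc_y != 0)) osc_y <- osc_y - mean(osc_y)
    if (any(osc_z != 0)) osc_z <- osc_z - mean(osc_z)

    noise <- function() {
      if (profile$noise_sd > 0) stats::rnorm(n, 0, profile$noise_sd) else 0
    }
    ax <- profile$ap_baseline + osc_x + noise()
    ay <- profile$vertical_baseline + osc_y + noise()
    az <- profile$ml_baseline + osc_z + noise()

    tracing <- structure(list(
      subject_id = subject_id,
      rate_hz = rate_hz,
      data = data.frame(sample_index = seq_len(n) - 1L,
                        ax_g = ax, ay_g = ay, az_g = az)
    ), class = "raw_tracing")

    truth <- structure(list(
      subject_id = subject_id,
      true_cadence = profile$cadence_mean,
      true_step_time_sd = profile$step_time_cv_within * tau_mean,
      true_ml_sway_amp = profile$ml_sway_amp,
      step_times = step_times,
      turn_times = turn_starts,
      turn_duration_s = profile$turn_duration_s,
      pause_times = pause_starts,
      pause_duration_s = profile$pause_duration_s,
      label = label
    ), class = "ground_truth")

    list(tracing = tracing, truth = truth)
  })
}

# cosine-ramped gate: 1 outside the [starts, ends] intervals, 0 inside
smooth_gate <- function(t, starts, ends, ramp_s = 0.2) {
  g <- rep(1, length(t))
  for (i in seq_along(starts)) {
    a <- starts[i]; b <- ends[i]
    gi <- rep(1, length(t))
    gi[t >= a & t <= b] <- 0
    rin <- t >= a - ramp_s & t < a
    gi[rin] <- 0.5 * (1 + cos(pi * (t[rin] - (a - ramp_s)) / ramp_s))
    rout <- t > b & t <= b + ramp_s
    gi[rout] <- 0.5 * (1 - cos(pi * (t[rout] - b) / ramp_s))
    g <- pmin(g, gi)
  }
  g
}

# white noise passed through a 2nd-order low-pass Butterworth filter
lowpass_noise <- function(n, rate_hz, cutoff_hz) {
  bf <- signal::butter(2, min(cutoff_hz / (rate_hz / 2), 0.99), type = "low")
  as.numeric(signal::filtfilt(bf, stats::rnorm(n)))
}

#' Simulate a labelled cohort of walking tracings
#'
#' Draws per-subject cadence from each archetype's between-subject
#' distribution (truncated at 60 steps/min), simulates every subject's
#' tracing with a per-subject random stream derived from the master seed,
#' and builds a cohort table whose Short Physical Performance Battery
#' (SPPB) totals and past-year fall counts are consistent with the risk
#' labels: high-risk subjects have SPPB <= 9 and at least one fall,
#' low-risk subjects SPPB 10-12 and no falls.
#'
#' @param spec A [cohort_spec()].
#'
#' @return A list with `tracings` (list of `raw_tracing`), `cohort`
#'   (data frame: subject_id, age, sppb_total, falls_past_year, label)
#'   and `truths` (list of `ground_truth`).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n_tot <- spec$n_high + spec$n_low
  if (n_tot == 0) stop_input("empty cohort: n_high + n_low must be > 0")
  labels <- rep(c("high", "low"), c(spec$n_high, spec$n_low))
  ids <- sprintf("S%03d", seq_len(n_tot))

  draws <- with_seed(spec$seed, {
    cad <- numeric(n_tot)
    sppb <- integer(n_tot)
    falls <- integer(n_tot)
    age <- numeric(n_tot)
    for (i in seq_len(n_tot)) {
      pr <- if (labels[i] == "high") spec$high_profile else spec$low_profile
      cad[i] <- max(60, stats::rnorm(1, pr$cadence_mean,
                                     pr$cadence_sd_between_subjects))
      if (labels[i] == "high") {
        sppb[i] <- sample(6:9, 1, prob = c(0.10, 0.15, 0.10, 0.65))
        falls[i] <- sample(1:3, 1, prob = c(0.684, 0.211, 0.105))
        age[i] <- stats::rnorm(1, 77.3, 5.9)
      } else {
        sppb[i] <- sample(10:12, 1, prob = c(0.45, 0.30, 0.25))
        falls[i] <- 0L
        age[i] <- stats::rnorm(1, 77.6, 6.2)
      }
    }
    list(cad = cad, sppb = sppb, falls = falls, age = round(age, 1))
  })

  tracings <- vector("list", n_tot)
  truths <- vector("list", n_tot)
  for (i in seq_len(n_tot)) {
    pr <- if (labels[i] == "high") spec$high_profile else spec$low_profile
    pr$cadence_mean <- draws$cad[i]
    pr$cadence_sd_between_subjects <- 0
    pr <- do.call(gait_profile, unclass(pr))
    sim <- simulate_subject(pr, spec$duration_s, spec$rate_hz,
                            seed = subject_seed(spec$seed, i),
                            subject_id = ids[i], label = labels[i])
    tracings[[i]] <- sim$tracing
    truths[[i]] <- sim$truth
  }

  cohort <- data.frame(
    subject_id = ids,
    age = draws$age,
    sppb_total = draws$sppb,
    falls_past_year = draws$falls,
    stringsAsFactors = FALSE
  )
  cohort <- assign_risk_labels(cohort)
  stopifnot(identical(cohort$label, labels))

  list(tracings = tracings, cohort = cohort, truths = truths)
}
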