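# Constructors for small synthetic fixtures used across test files.

# a gait_window built directly from axis series
make_window <- function(x, y, z, rate_hz = 30, subject_id = "T",
                        window_index = 1L) {
  structure(list(
    subject_id = subject_id,
    window_index = window_index,
    start_sample = 0L,
    rate_hz = rate_hz,
    x = x, y = y, z = z,
    vm = sqrt(x^2 + y^2 + z^2)
  ), class = "gait_window")
}

# a hand-built walking mask
make_mask <- function(mask) {
  structure(list(mask = mask, walking_fraction = mean(mask),
                 params = list()), class = "walking_mask")
}

# a clean 10 s "steady walking" window: 2 Hz vector-magnitude
# periodicity riding on gravity along y
steady_walk_window <- function(rate_hz = 30, step_hz = 2, amp = 0.4,
                               n_s = 10) {
  t <- (0:(n_s * rate_hz - 1)) / rate_hz
  y <- -1 - amp * sin(2 * pi * step_hz * t + 0.3)
  make_window(rep(0, length(t)), y, rep(0, length(t)), rate_hz)
}

# a raw_tracing from axis vectors
make_tracing <- function(ax, ay, az, rate_hz = 30, subject_id = "T") {
  structure(list(
    subject_id = subject_id,
    rate_hz = rate_hz,
    data = data.frame(sample_index = seq_along(ax) - 1L,
                      ax_g = ax, ay_g = ay, az_g = az)
  ), class = "raw_tracing")
}

# profile with no turns/pauses and optional zero noise, for recovery tests
clean_profile <- function(cadence = 120, cv = 0, noise_sd = 0, ...) {
  gait_profile(cadence_mean = cadence, cadence_sd_between_subjects = 0,
               step_time_cv_within = cv, noise_sd = noise_sd,
               turn_duration_s = 0, pause_prob_per_lap = 0, ...)
}

# a separable two-class feature frame: one informative feature plus noise
separable_features <- function(n_per_class = 60, n_noise = 4, seed = 1,
                               gap = 3) {
  withr::with_seed(seed, {
    n <- 2 * n_per_class
    lab <- rep(c("high", "low"), each = n_per_class)
    df <- data.frame(subject_id = sprintf("S%03d", seq_len(n)),
                     label = lab, stringsAsFactors = FALSE)
    df$F1 <- runif(n) + ifelse(lab == "low", gap, 0)
    for (j in seq_len(n_noise)) df[[paste0("N", j)]] <- rnorm(n)
    df
  })
}
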