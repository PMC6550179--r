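#' The 52-name feature catalog
#'
#' Eleven signal features for each of the four series (X =
#' anteroposterior, Y = vertical, Z = mediolateral, MAG = vector
#' magnitude), three zero-lag cross-axis correlations, and five
#' traditional gait measures.
#'
#' @return Character vector of 52 feature names.
#' @export
feature_catalog <- function() {
  sig <- c("MEAN", "STD", "RMS", "ACC", "COV", "MCR", "SMA", "P2P",
           "PFREQ", "ENERGY", "MAD")
  c(
    as.vector(t(outer(c("X", "Y", "Z", "MAG"), sig, paste, sep = "_"))),
    c("XY_CORR", "YZ_CORR", "XZ_CORR"),
    gait_feature_names()
  )
}

gait_feature_names <- function() {
  c("CADENCE", "MEAN_STEP_TIME", "STD_STEP_TIME",
    "MEAN_STRIDE_TIME", "STD_STRIDE_TIME")
}

#' Time- and frequency-domain signal features of one series
#'
#' Computes the eleven per-series features:
#' \describe{
#'   \item{MEAN}{arithmetic mean (g)}
#'   \item{STD}{population standard deviation (g)}
#'   \item{RMS}{root mean square, so `RMS^2 = MEAN^2 + STD^2` (g)}
#'   \item{ACC}{normalized autocorrelation at the dominant period
#'     (lag `round(rate / PFREQ)`; set `acc_lag = "one"` for plain
#'     lag-1)}
#'   \item{COV}{signed coefficient of variation `STD / MEAN`; a zero
#'     mean yields an infinite sentinel, left unguarded on purpose}
#'   \item{MCR}{mean-crossing rate: crossings of the series mean per
#'     second}
#'   \item{SMA}{signal magnitude area, per-series form: mean absolute
#'     value (g)}
#'   \item{P2P}{peak-to-peak amplitude `max - min` (g)}
#'   \item{PFREQ}{frequency of the largest non-DC spectral magnitude of
#'     the mean-removed series, rectangular window, no zero padding,
#'     ties toward the lower frequency (Hz)}
#'   \item{ENERGY}{mean squared mean-removed sample — the DC-excluded
#'     spectral energy by Parseval's identity (g^2)}
#'   \item{MAD}{mean absolute deviation from the mean (g)}
#' }
#' For a constant series, PFREQ and ACC are undefined and returned as
#' `NA`.
#'
#' @param series Numeric acceleration series in g, length >= 30.
#' @param rate_hz Sampling rate, Hz.
#' @param acc_lag `"dominant"` (default) or `"one"`.
#' @return Named numeric vector of the 11 features.
#' @export
signal_features <- function(series, rate_hz, acc_lag = c("dominant", "one")) {
  acc_lag <- match.arg(acc_lag)
  n <- length(series)
  if (n < 30) stop_input("series must have >= 30 samples (got %d)", n)
  if (any(!is.finite(series))) stop_input("series must be finite")
  m <- mean(series)
  s <- series - m
  std <- sqrt(mean(s^2))
  rms <- sqrt(mean(series^2))
  cov <- std / m
  mcr <- sum(s[-n] * s[-1] < 0) / (n / rate_hz)
  sma <- mean(abs(series))
  p2p <- max(series) - min(series)
  mad <- mean(abs(s))
  energy <- mean(s^2)
  if (std == 0) {
    pfreq <- NA_real_
    acc <- NA_real_
  } else {
    mag <- Mod(stats::fft(s))
    k <- seq_len(floor(n / 2))
    pfreq <- k[which.max(mag[k + 1L])] * rate_hz / n
    lag <- if (acc_lag == "dominant") {
      min(max(1L, as.integer(round(rate_hz / pfreq))), n - 1L)
    } else 1L
    acc <- sum(s[1:(n - lag)] * s[(1 + lag):n]) / sum(s^2)
  }
  c(MEAN = m, STD = std, RMS = rms, ACC = acc, COV = cov, MCR = mcr,
    SMA = sma, P2P = p2p, PFREQ = pfreq, ENERGY = energy, MAD = mad)
}

#' Zero-lag cross-axis correlations over walking samples
#'
#' Pearson correlations between the axis pairs, computed over the
#' masked-true samples only. An undefined correlation (either series
#' constant) is reported as 0 and flagged.
#'
#' @param window A `gait_window`.
#' @param mask Its `walking_mask`.
#' @return Named vector `XY_CORR`, `YZ_CORR`, `XZ_CORR` with attribute
#'   `flagged` naming undefined entries.
#' @export
cross_axis_correlations <- function(window, mask) {
  keep <- mask$mask
  if (sum(keep) < 30) stop_input("need >= 30 walking samples (got %d)", sum(keep))
  x <- window$x[keep]; y <- window$y[keep]; z <- window$z[keep]
  safe_cor <- function(a, b) {
    if (sd_pop(a) == 0 || sd_pop(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }
  out <- c(XY_CORR = safe_cor(x, y), YZ_CORR = safe_cor(y, z),
           XZ_CORR = safe_cor(x, z))
  flagged <- names(out)[is.na(out)]
  out[is.na(out)] <- 0
  attr(out, "flagged") <- flagged
  out
}

#' Detect step events within the walking runs of a window
#'
#' Band-passes the vertical axis to the locomotor band within each
#' contiguous walking run, then takes local maxima with a minimum
#' inter-peak separation of 0.25 s and a height of at least half the
#' run's band-passed standard deviation. Peak times are refined to
#' sub-sample precision by parabolic interpolation, so step-interval
#' statistics are not limited by the 1/30 s sampling grid. Runs shorter
#' than 2 s are skipped; events never bridge masked-out gaps.
#'
#' @param window A `gait_window`.
#' @param mask Its `walking_mask`.
#' @param rate_hz Sampling rate, Hz.
#' @param band Pass band for the vertical series, Hz.
#' @return A `step_events` object: data frame with `time` (seconds from
#'   window start, strictly increasing) and `run` (run id); fewer than 4
#'   events means the window's gait features are treated as missing.
#' @export
detect_steps <- function(window, mask, rate_hz = window$rate_hz,
                         band = c(0.5, 3.5)) {
  runs <- extract_good_runs(window, mask, min_walking_fraction = 0)$runs
  min_sep <- round(0.25 * rate_hz)
  events <- list()
  bf <- signal::butter(2, band / (rate_hz / 2), type = "pass")
  for (r in seq_len(nrow(runs))) {
    seg <- window$y[runs$start[r]:runs$end[r]]
    if (length(seg) < 2 * rate_hz) next
    bp <- as.numeric(signal::filtfilt(bf, seg - mean(seg)))
    pk <- find_peaks(bp, min_height = 0.5 * sd_pop(bp), min_sep = min_sep)
    if (!length(pk)) next
    # parabolic sub-sample refinement of each peak position
    delta <- vapply(pk, function(p) {
      if (p <= 1 || p >= length(bp)) return(0)
      den <- bp[p - 1] - 2 * bp[p] + bp[p + 1]
      if (den == 0) return(0)
      max(min(0.5 * (bp[p - 1] - bp[p + 1]) / den, 0.5), -0.5)
    }, numeric(1))
    events[[length(events) + 1L]] <- data.frame(
      time = (runs$start[r] - 1L + pk - 1L + delta) / rate_hz,
      run = r
    )
  }
  ev <- if (length(events)) do.call(rbind, events) else {
    data.frame(time = numeric(0), run = integer(0))
  }
  structure(ev, class = c("step_events", "data.frame"))
}

# local maxima above a height, thinned to a minimum separation by
# keeping higher peaks first
find_peaks <- function(x, min_height, min_sep) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  cand <- cand[x[cand] >= min_height]
  if (!length(cand)) return(integer(0))
  cand <- cand[order(-x[cand])]
  kept <- integer(0)
  for (p in cand) {
    if (!length(kept) || all(abs(kept - p) >= min_sep)) kept <- c(kept, p)
  }
  sort(kept)
}

#' Traditional gait measures from step events
#'
#' Step times are differences between consecutive events of the same
#' run; stride times are differences between alternating events (both
#' parities pooled), again within runs. Cadence is `60 / MEAN_STEP_TIME`
#' steps/min. All SDs use the population convention. Fewer than 4 events
#' yields all-`NA` gait features.
#'
#' @param events A `step_events` object or a numeric vector of event
#'   times (treated as one run).
#' @return Named vector `CADENCE`, `MEAN_STEP_TIME`, `STD_STEP_TIME`,
#'   `MEAN_STRIDE_TIME`, `STD_STRIDE_TIME`.
#' @export
gait_features <- function(events) {
  if (is.numeric(events)) {
    events <- data.frame(time = as.numeric(events),
                         run = rep(1L, length(events)))
  }
  out <- stats::setNames(rep(NA_real_, 5), gait_feature_names())
  if (nrow(events) < 4) return(out)
  steps <- unlist(lapply(split(events$time, events$run), diff),
                  use.names = FALSE)
  strides <- unlist(lapply(split(events$time, events$run), function(tm) {
    if (length(tm) < 3) return(numeric(0))
    tm[-(1:2)] - tm[seq_len(length(tm) - 2)]
  }), use.names = FALSE)
  if (!length(steps)) return(out)
  out["MEAN_STEP_TIME"] <- mean(steps)
  out["STD_STEP_TIME"] <- sd_pop(steps)
  out["CADENCE"] <- 60 / mean(steps)
  if (length(strides)) {
    out["MEAN_STRIDE_TIME"] <- mean(strides)
    out["STD_STRIDE_TIME"] <- sd_pop(strides)
  }
  out
}

#' Feature row for one accepted window
#'
#' Computes the full 52-feature row: the 11 signal features of each axis
#' and of the vector magnitude over the concatenated walking samples,
#' the three cross-axis correlations, and the five gait measures from
#' step events detected within contiguous walking runs.
#'
#' @param window A `gait_window` accepted by [extract_good_runs()].
#' @param mask Its `walking_mask`.
#' @param events Optional precomputed [detect_steps()] result.
#' @param acc_lag Passed to [signal_features()].
#' @return One-row data frame: `subject_id`, `window_index`, the 52
#'   features, and `n_steps` (detected events, for QC).
#' @export
featurize_window <- function(window, mask, events = NULL,
                             acc_lag = "dominant") {
  keep <- mask$mask
  series <- list(X = window$x[keep], Y = window$y[keep],
                 Z = window$z[keep], MAG = window$vm[keep])
  sig <- unlist(lapply(names(series), function(nm) {
    v <- signal_features(series[[nm]], window$rate_hz, acc_lag = acc_lag)
    stats::setNames(v, paste(nm, names(v), sep = "_"))
  }))
  corr <- cross_axis_correlations(window, mask)
  if (is.null(events)) events <- detect_steps(window, mask)
  gait <- gait_features(events)
  row <- data.frame(subject_id = window$subject_id,
                    window_index = window$window_index,
                    t(c(sig, corr, gait)),
                    n_steps = nrow(events),
                    check.names = FALSE,
                    stringsAsFactors = FALSE)
  rownames(row) <- NULL
  row
}

#' Preprocess and featurize one tracing
#'
#' Runs the full per-subject path: segmentation into 10 s windows with
#' 50% overlap, the vm-standard-deviation inactivity filter, the
#' good-walking mask, the walking-fraction acceptance rule, and feature
#' extraction for accepted windows.
#'
#' @param tracing A `raw_tracing`.
#' @param window_s,overlap Segmentation parameters.
#' @param vm_std_threshold Inactivity threshold, g.
#' @param min_walking_fraction Window acceptance threshold.
#' @param acc_lag Passed to [signal_features()].
#' @return List with `features` (data frame, one row per accepted
#'   window) and `qc` (one row per window: vm_std, walking_fraction,
#'   active and accepted flags).
#' @export
featurize_tracing <- function(tracing, window_s = 10, overlap = 0.5,
                              vm_std_threshold = 0.01,
                              min_walking_fraction = 0.5,
                              acc_lag = "dominant") {
  windows <- segment_windows(tracing, window_s, overlap)
  if (!length(windows)) {
    return(list(features = NULL,
                qc = data.frame(subject_id = character(0))))
  }
  vm_std <- vapply(windows, function(w) sd_pop(w$vm), numeric(1))
  active <- vm_std >= vm_std_threshold
  rows <- list()
  wf <- rep(NA_real_, length(windows))
  accepted <- rep(FALSE, length(windows))
  for (i in seq_along(windows)) {
    if (!active[i]) next
    mask <- good_walking_mask(windows[[i]],
                              vm_std_threshold = vm_std_threshold)
    wf[i] <- mask$walking_fraction
    gr <- extract_good_runs(windows[[i]], mask, min_walking_fraction)
    accepted[i] <- gr$accepted
    if (!gr$accepted) next
    rows[[length(rows) + 1L]] <- featurize_window(windows[[i]], mask,
                                                  acc_lag = acc_lag)
  }
  qc <- data.frame(
    subject_id = tracing$subject_id,
    window_index = seq_along(windows),
    vm_std = vm_std,
    walking_fraction = wf,
    active = active,
    accepted = accepted,
    stringsAsFactors = FALSE
  )
  features <- if (length(rows)) do.call(rbind, rows) else NULL
  list(features = features, qc = qc)
}

#' Featurize a whole cohort
#'
#' Applies [featurize_tracing()] to every tracing and attaches each
#' subject's risk label from the cohort table.
#'
#' @param tracings List of `raw_tracing`s.
#' @param cohort Cohort table with `subject_id` and `label`.
#' @param ... Passed to [featurize_tracing()].
#' @return List with `features` (rows from all accepted windows, with a
#'   `label` column) and `qc` (per-window QC rows).
#' @export
featurize_cohort <- function(tracings, cohort, ...) {
  stopifnot(all(c("subject_id", "label") %in% names(cohort)))
  feats <- list(); qcs <- list()
  for (tr in tracings) {
    res <- featurize_tracing(tr, ...)
    if (!is.null(res$features)) feats[[length(feats) + 1L]] <- res$features
    qcs[[length(qcs) + 1L]] <- res$qc
  }
  features <- if (length(feats)) do.call(rbind, feats) else NULL
  if (!is.null(features)) {
    features$label <- cohort$label[match(features$subject_id,
                                         cohort$subject_id)]
  }
  list(features = features,
       qc = do.call(rbind, qcs))
}
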