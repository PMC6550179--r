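#' Per-sample vector magnitude
#'
#' Euclidean norm of the three acceleration axes, in g: the square root
#' of the sum of the squared x, y and z accelerations.
#'
#' @param ax,ay,az Accelerations in g (vectorized).
#' @return Non-negative numeric vector of magnitudes, g.
#' @examples
#' vector_magnitude(0, 0, -1)    # 1
#' vector_magnitude(0.6, 0.8, 0) # 1
#' @export
vector_magnitude <- function(ax, ay, az) {
  stopifnot(all(is.finite(ax)), all(is.finite(ay)), all(is.finite(az)))
  sqrt(ax^2 + ay^2 + az^2)
}

#' Segment a tracing into overlapping windows
#'
#' Splits a tracing into fixed-length windows (default 10 s = 300
#' samples at 30 Hz) with 50% overlap. Only full-length windows are
#' emitted; trailing samples that do not fill a window are dropped.
#'
#' @param tracing A `raw_tracing`.
#' @param window_s Window length, s.
#' @param overlap Fractional overlap between consecutive windows.
#' @return List of `gait_window` objects, each carrying the axis series,
#'   the per-sample vector magnitude `vm`, the 0-based `start_sample`
#'   and a 1-based `window_index`.
#' @export
segment_windows <- function(tracing, window_s = 10, overlap = 0.5) {
  stopifnot(inherits(tracing, "raw_tracing"))
  if (window_s <= 0) stop_input("window_s must be > 0")
  if (overlap < 0 || overlap >= 1) stop_input("overlap must be in [0, 1)")
  rate <- tracing$rate_hz
  len <- round(window_s * rate)
  step <- round(len * (1 - overlap))
  n <- nrow(tracing$data)
  if (n < len) return(list())
  starts <- seq(1L, n - len + 1L, by = step)
  vm <- vector_magnitude(tracing$data$ax_g, tracing$data$ay_g,
                         tracing$data$az_g)
  lapply(seq_along(starts), function(i) {
    idx <- starts[i]:(starts[i] + len - 1L)
    structure(list(
      subject_id = tracing$subject_id,
      window_index = i,
      start_sample = starts[i] - 1L,
      rate_hz = rate,
      x = tracing$data$ax_g[idx],
      y = tracing$data$ay_g[idx],
      z = tracing$data$az_g[idx],
      vm = vm[idx]
    ), class = "gait_window")
  })
}

#' Discard inactive windows
#'
#' A window is discarded iff the population standard deviation of its
#' vector magnitude is strictly below the threshold (default 0.01 g),
#' removing periods of inactivity before any walking detection runs.
#'
#' @param windows List of `gait_window` objects.
#' @param vm_std_threshold Threshold on the vm standard deviation, g.
#' @return List with elements `retained` and `discarded` (both lists of
#'   windows); together they partition the input.
#' @export
filter_inactive <- function(windows, vm_std_threshold = 0.01) {
  stds <- vapply(windows, function(w) sd_pop(w$vm), numeric(1))
  keep <- stds >= vm_std_threshold
  list(retained = windows[keep], discarded = windows[!keep],
       vm_std = stds)
}

#' Good-walking mask for one window
#'
#' Classifies 1 s sub-windows (30 samples at 30 Hz, stride 15) of the
#' window as walking or non-walking; a sample counts as walking iff
#' every sub-window covering it is walking.
#' A sub-window counts as walking iff, over a 2 s context centred on it:
#' (a) the vm standard deviation is at or above the inactivity
#' threshold, (b) the dominant (non-DC) frequency of the mean-removed vm
#' lies in the locomotor band, and (c) the maximum normalized
#' autocorrelation over lags of 0.25-1.0 s reaches `acf_min` — i.e. the
#' signal is active, periodic, and periodic at a plausible step rate.
#' Turns show up as aperiodic magnitude drops and fail (b)/(c); pauses
#' fail (a) or (c). The first and last 15 samples of every window are
#' always marked non-walking: they lack the context to be classified.
#'
#' @param window A `gait_window` (should already have passed
#'   [filter_inactive()]).
#' @param vm_std_threshold Activity threshold on vm SD, g.
#' @param freq_range Allowed dominant-frequency band, Hz.
#' @param acf_lags_s Lag range for the periodicity check, s.
#' @param acf_min Minimum normalized autocorrelation.
#' @param sub_window_s,sub_stride_s Sub-window length and stride, s.
#' @return A `walking_mask`: list with logical `mask`,
#'   `walking_fraction`, and the parameters used.
#' @export
good_walking_mask <- function(window, vm_std_threshold = 0.01,
                              freq_range = c(1, 3),
                              acf_lags_s = c(0.25, 1.0),
                              acf_min = 0.3,
                              sub_window_s = 1, sub_stride_s = 0.5) {
  stopifnot(inherits(window, "gait_window"))
  rate <- window$rate_hz
  vm <- window$vm
  len <- length(vm)
  sw <- round(sub_window_s * rate)
  st <- round(sub_stride_s * rate)
  starts <- seq(1L, len - sw + 1L, by = st)
  lag_lo <- max(1L, round(acf_lags_s[1] * rate))
  lag_hi <- round(acf_lags_s[2] * rate)
  walk_sub <- vapply(starts, function(s0) {
    s1 <- s0 + sw - 1L
    # 2 s context centred on the sub-window for the spectral and
    # autocorrelation checks (a 1 s piece has too few long-lag pairs)
    c0 <- max(1L, s0 - st)
    c1 <- min(len, s1 + st)
    ctx <- vm[c0:c1]
    if (sd_pop(vm[s0:s1]) < vm_std_threshold) return(FALSE)
    dom <- dominant_frequency(ctx, rate)
    if (is.na(dom) || dom < freq_range[1] || dom > freq_range[2]) {
      return(FALSE)
    }
    max_acf(ctx, lag_lo, lag_hi) >= acf_min
  }, logical(1))
  # a sample is walking iff every sub-window covering it is walking:
  # intersection semantics keep the context window from bleeding
  # "walking" into the edges of turns and pauses
  mask <- rep(TRUE, len)
  covered <- rep(FALSE, len)
  for (j in seq_along(starts)) {
    idx <- starts[j]:(starts[j] + sw - 1L)
    mask[idx] <- mask[idx] & walk_sub[j]
    covered[idx] <- TRUE
  }
  mask[!covered] <- FALSE
  edge <- min(15L, len)
  mask[seq_len(edge)] <- FALSE
  mask[(len - edge + 1L):len] <- FALSE
  structure(list(
    mask = mask,
    walking_fraction = mean(mask),
    params = list(vm_std_threshold = vm_std_threshold,
                  freq_range = freq_range, acf_lags_s = acf_lags_s,
                  acf_min = acf_min)
  ), class = "walking_mask")
}

# frequency (Hz) of the largest non-DC spectral magnitude of the
# mean-removed series; ties resolve to the lower frequency
dominant_frequency <- function(x, rate_hz) {
  n <- length(x)
  if (n < 4 || sd_pop(x) == 0) return(NA_real_)
  mag <- Mod(stats::fft(x - mean(x)))
  k <- seq_len(floor(n / 2))
  k[which.max(mag[k + 1L])] * rate_hz / n
}

# maximum normalized (biased) autocorrelation over a lag range
max_acf <- function(x, lag_lo, lag_hi) {
  n <- length(x)
  s <- x - mean(x)
  denom <- sum(s^2)
  if (denom == 0) return(0)
  lags <- lag_lo:min(lag_hi, n - 2L)
  if (!length(lags)) return(0)
  max(vapply(lags, function(l) {
    sum(s[1:(n - l)] * s[(1 + l):n]) / denom
  }, numeric(1)))
}

#' Accept a window and list its contiguous good-walking runs
#'
#' A window is accepted iff its walking fraction reaches
#' `min_walking_fraction`; accepted windows carry the maximal contiguous
#' runs of walking samples, which downstream gait features never bridge.
#'
#' @param window A `gait_window`.
#' @param mask Its `walking_mask`.
#' @param min_walking_fraction Minimum fraction of walking samples.
#' @return List with `accepted` (logical), `walking_fraction`, and
#'   `runs`, a data frame of 1-based `start`, `end`, `length` for each
#'   maximal run of walking samples.
#' @export
extract_good_runs <- function(window, mask, min_walking_fraction = 0.5) {
  stopifnot(inherits(mask, "walking_mask"))
  wf <- mask$walking_fraction
  r <- rle(mask$mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  runs <- data.frame(start = starts[keep], end = ends[keep],
                     length = r$lengths[keep])
  list(accepted = wf >= min_walking_fraction,
       walking_fraction = wf,
       runs = runs)
}

#' Combine per-window masks into a per-sample tracing mask
#'
#' Because windows overlap by 50%, a sample that sits in the forced
#' non-walking edge of one window is interior to its neighbour; the
#' tracing-level mask is the union (logical OR) of all window masks and
#' is the natural object for judging mask quality against a simulator's
#' known turn and pause schedule.
#'
#' @param tracing The `raw_tracing` the windows came from.
#' @param windows List of `gait_window`s from [segment_windows()].
#' @param masks List of `walking_mask`s, parallel to `windows`.
#' @return Logical vector, one entry per tracing sample.
#' @export
combine_window_masks <- function(tracing, windows, masks) {
  out <- rep(FALSE, nrow(tracing$data))
  for (i in seq_along(windows)) {
    w <- windows[[i]]
    idx <- (w$start_sample + 1L):(w$start_sample + length(w$vm))
    out[idx] <- out[idx] | masks[[i]]$mask
  }
  out
}
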