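#' @keywords internal
"_PACKAGE"

# population (denominator n) standard deviation; pinned convention so that
# RMS^2 = MEAN^2 + STD^2 holds exactly for every series
sd_pop <- function(x) {
  sqrt(mean((x - mean(x))^2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(sprintf(...), call. = FALSE)

# run expr with a fixed RNG state, restoring the caller's stream afterwards
with_seed <- function(seed, expr) {
  withr::with_seed(seed, expr)
}

# derive a per-subject stream from the master seed; kept inside 32-bit range
subject_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + i) %% .Machine$integer.max)
}

entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}
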