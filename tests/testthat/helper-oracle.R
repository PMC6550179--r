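# Brute-force reference implementations of the signal features, written
# directly from their definitions (explicit sums, naive DFT) and kept
# independent of the package's computation path.

oracle_signal_features <- function(x, rate_hz, acc_lag = "dominant") {
  n <- length(x)
  m <- sum(x) / n
  s <- x - m
  std <- sqrt(sum(s^2) / n)
  rms <- sqrt(sum(x^2) / n)
  cov <- std / m
  crossings <- 0
  for (i in 1:(n - 1)) {
    if (s[i] * s[i + 1] < 0) crossings <- crossings + 1
  }
  mcr <- crossings / (n / rate_hz)
  sma <- sum(abs(x)) / n
  p2p <- max(x) - min(x)
  mad <- sum(abs(s)) / n
  energy <- sum(s^2) / n
  if (std == 0) {
    pfreq <- NA_real_
    acc <- NA_real_
  } else {
    # naive DFT magnitude, bins 1 .. floor(n/2); first maximal bin wins
    ks <- seq_len(floor(n / 2))
    mags <- vapply(ks, function(k) {
      re <- sum(s * cos(2 * pi * k * (0:(n - 1)) / n))
      im <- sum(s * sin(2 * pi * k * (0:(n - 1)) / n))
      sqrt(re^2 + im^2)
    }, numeric(1))
    kbest <- ks[which.max(mags)]
    pfreq <- kbest * rate_hz / n
    lag <- if (acc_lag == "dominant") {
      min(max(1L, as.integer(round(rate_hz / pfreq))), n - 1L)
    } else 1L
    acc <- sum(s[1:(n - lag)] * s[(1 + lag):n]) / sum(s^2)
  }
  c(MEAN = m, STD = std, RMS = rms, ACC = acc, COV = cov, MCR = mcr,
    SMA = sma, P2P = p2p, PFREQ = pfreq, ENERGY = energy, MAD = mad)
}

oracle_auc <- function(scores, is_pos) {
  # direct pairwise Mann-Whitney count with half-credit for ties
  pos <- scores[is_pos]
  neg <- scores[!is_pos]
  if (!length(pos) || !length(neg)) return(NA_real_)
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}
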