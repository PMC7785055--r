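# Direct double-summation Stockwell transform: the independent oracle
# for the FFT-based implementation. Evaluates, for every (f, tau) pair,
#   |sum_t x(t) * (kf/sqrt(2*pi)) * exp(-(tau-t)^2 kf^2 / 2)
#          * exp(-i 2 pi f t) * dt|       with kf = window_factor * f
# over the full, untruncated sample grid.
stransform_direct <- function(x, fs, freqs, window_factor = 1) {
  n <- length(x)
  dt <- 1 / fs
  tgrid <- (seq_len(n) - 1) * dt
  amp <- matrix(0, length(freqs), n)
  for (i in seq_along(freqs)) {
    f <- freqs[i]
    kf <- f * window_factor
    for (j in seq_len(n)) {
      tau <- tgrid[j]
      s <- sum(x * (kf / sqrt(2 * pi)) * exp(-(tau - tgrid)^2 * kf^2 / 2) *
                 exp(-2i * pi * f * tgrid)) * dt
      amp[i, j] <- Mod(s)
    }
  }
  amp
}

# Smooth single-beat pressure template: raised-cosine upstroke into an
# exponential relaxation fall, both channels built from the same shape so
# correlation-lag recovery has an exact ground truth.
make_pressure_beat <- function(n = 700, fs = 1000, rise_start_ms = 50,
                               rise_ms = 180, fall_tau_ms = 50,
                               base = 8, amp = 90, shift_ms = 0) {
  t <- (seq_len(n) - 1) * 1000 / fs - shift_ms
  s <- numeric(n)
  ris <- t >= rise_start_ms & t < rise_start_ms + rise_ms
  s[ris] <- 0.5 * (1 - cos(pi * (t[ris] - rise_start_ms) / rise_ms))
  fal <- t >= rise_start_ms + rise_ms
  s[fal] <- exp(-(t[fal] - rise_start_ms - rise_ms) / fall_tau_ms)
  hs_signal(base + amp * s, fs, units = "mmHg")
}

# sample-index lag of the peak cross-correlation between two equal-length
# vectors (positive: y lags x)
xcorr_peak_lag <- function(x, y, max_lag = 50) {
  lags <- (-max_lag):max_lag
  cc <- vapply(lags, function(k) {
    if (k >= 0) sum(x[seq_len(length(x) - k)] * y[seq_len(length(y) - k) + k])
    else sum(x[seq_len(length(x) + k) - k] * y[seq_len(length(y) + k)])
  }, numeric(1))
  lags[which.max(cc)]
}
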