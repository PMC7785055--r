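test_that("hs_signal validates its fields", {
  expect_error(hs_signal(numeric(0), 1000), "at least one sample")
  expect_error(hs_signal(c(1, NA), 1000), "finite")
  expect_error(hs_signal(1:10, -5), "positive")
  s <- hs_signal(1:11, fs = 10)
  expect_equal(signal_duration(s), 1)
  expect_equal(signal_times(s)[2], 0.1)
  expect_length(s, 11L)
})

test_that("CSV round trip is lossless and infers the sampling rate", {
  x <- sin(2 * pi * 7 * (0:99) / 250)
  s <- hs_signal(x, fs = 250)
  path <- withr::local_tempfile(fileext = ".csv")
  write_signal(s, path)
  back <- read_signal(path)
  expect_identical(back$samples, x)
  expect_equal(back$fs, 250)
})

test_that("CSV reader handles the millisecond grid and rejects non-uniform axes", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("0.000,0.0", "0.001,1.0", "0.002,0.0"), path)
  s <- read_signal(path)
  expect_equal(s$fs, 1000)
  expect_length(s, 3L)

  writeLines(c("time,value", "0.000,0", "0.001,1", "0.003,0", "0.004,1"),
             path)
  expect_error(read_signal(path), "non-uniform")
})

test_that("WAV round trip preserves fs and samples within 16-bit quantisation", {
  x <- sin(2 * pi * 5 * (0:59) / 1000)
  s <- hs_signal(x / max(abs(x)), fs = 1000)
  path <- withr::local_tempfile(fileext = ".wav")
  write_signal(s, path)
  back <- read_signal(path)
  expect_equal(back$fs, 1000)
  expect_length(back, 60L)
  expect_lt(max(abs(back$samples - s$samples)), 1 / 32768)
  expect_error(read_signal(path, channel = 2), "channel")
})

test_that("bandpass attenuates the stopband and passes the passband", {
  fs <- 1000
  t <- (0:999) / fs
  low_tone <- hs_signal(sin(2 * pi * 10 * t), fs)
  out <- bandpass(low_tone, 50, 250)
  expect_lt(sqrt(mean(out$samples^2)), 0.05 * sqrt(mean(low_tone$samples^2)))

  mid_tone <- hs_signal(sin(2 * pi * 150 * t), fs)
  out2 <- bandpass(mid_tone, 50, 250)
  core <- 101:900  # discard 100 ms edges
  expect_equal(sqrt(mean(out2$samples[core]^2)),
               sqrt(mean(mid_tone$samples[core]^2)),
               tolerance = 0.1)

  zero <- hs_signal(rep(0, 500), fs)
  expect_equal(bandpass(zero, 50, 250)$samples, rep(0, 500))

  expect_error(bandpass(mid_tone, 50, 600), "Nyquist")
})

test_that("filtering is zero-phase and linear", {
  fs <- 1000
  set.seed(42)
  x <- stats::filter(rnorm(2000), rep(0.2, 5), sides = 2)
  x[is.na(x)] <- 0
  s <- hs_signal(as.numeric(x), fs)
  y <- bandpass(s, 50, 250)
  lag <- xcorr_peak_lag(bandpass(y, 50, 250)$samples, y$samples)
  expect_identical(lag, 0L)

  set.seed(7)
  a <- hs_signal(rnorm(500), fs)
  b <- hs_signal(rnorm(500), fs)
  lhs <- bandpass(hs_signal(2 * a$samples + 3 * b$samples, fs), 50, 250)
  rhs <- 2 * bandpass(a, 50, 250)$samples + 3 * bandpass(b, 50, 250)$samples
  expect_equal(lhs$samples, rhs, tolerance = 1e-9)
})

test_that("highpass removes rumble and keeps in-band content", {
  fs <- 1000
  t <- (0:999) / fs
  s <- hs_signal(sin(2 * pi * 10 * t) + sin(2 * pi * 150 * t), fs)
  out <- highpass(s, 50)
  core <- 101:900
  resid <- out$samples[core] - sin(2 * pi * 150 * t)[core]
  expect_lt(sqrt(mean(resid^2)), 0.1)
})
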