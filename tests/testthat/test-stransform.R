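test_that("an all-zero snippet gives an all-zero spectrum", {
  s <- hs_signal(rep(0, 64), 1000)
  spec <- stransform(s, 50, 250, 10)
  expect_true(all(spec$amplitudes == 0))
  expect_equal(dim(spec$amplitudes), c(21L, 64L))
  expect_equal(spec$times_ms, 0:63)
})

test_that("a stationary tone peaks at its own frequency row", {
  fs <- 1000
  s <- hs_signal(sin(2 * pi * 150 * (0:999) / fs), fs)
  spec <- stransform(s, 50, 250, 1)
  interior <- which(spec$times_ms >= 100 & spec$times_ms <= 900)
  peak_freq <- spec$freqs[apply(spec$amplitudes[, interior], 2, which.max)]
  expect_true(all(abs(peak_freq - 150) <= 1))
  # up to floating-point ripple the row is unimodal along time: one
  # interior plateau maximum once the ripple is rounded away
  row150 <- spec$amplitudes[spec$freqs == 150, ]
  m <- s2split:::row_local_maxima(round(row150, 9))
  expect_length(m, 1L)
  expect_gt(spec$times_ms[m], 0)
  expect_lt(spec$times_ms[m], 999)
})

test_that("the FFT implementation matches the direct-summation oracle", {
  fs <- 1000
  for (case in list(c(n = 64, seed = 1, wf = 1),
                    c(n = 128, seed = 2, wf = 1),
                    c(n = 256, seed = 3, wf = 1),
                    c(n = 128, seed = 4, wf = 1.5))) {
    set.seed(case[["seed"]])
    x <- rnorm(case[["n"]])
    freqs <- seq(50, 250, by = 25)
    fast <- stransform(hs_signal(x, fs), 50, 250, 25,
                       window_factor = case[["wf"]])$amplitudes
    slow <- stransform_direct(x, fs, freqs, window_factor = case[["wf"]])
    expect_lt(max(abs(fast - slow)), 1e-8 * max(slow))
  }
})

test_that("amplitudes scale linearly with the input", {
  set.seed(5)
  x <- rnorm(100)
  fs <- 1000
  a1 <- stransform(hs_signal(x, fs), 50, 250, 20)$amplitudes
  a3 <- stransform(hs_signal(3 * x, fs), 50, 250, 20)$amplitudes
  expect_equal(a3, 3 * a1, tolerance = 1e-9)
})

test_that("an impulse is localised in every frequency row", {
  x <- rep(0, 128)
  x[70] <- 1
  spec <- stransform(hs_signal(x, 1000), 50, 250, 10)
  peaks <- apply(spec$amplitudes, 1, which.max)
  expect_true(all(abs(peaks - 70) <= 2))
})

test_that("stransform rejects invalid inputs", {
  s <- hs_signal(rnorm(64), 1000)
  expect_error(stransform(s, 50, 600, 1), "Nyquist")
  expect_error(stransform(hs_signal(rnorm(4), 1000), 50, 250, 1), "short")
  expect_error(stransform(s, 0, 250, 1), "fmin")
})

test_that("local maxima follow the strict-with-plateau rule", {
  mk <- function(rows) {
    structure(list(amplitudes = rows, freqs = seq_len(nrow(rows)) + 49,
                   times_ms = seq_len(ncol(rows)) - 1, fs = 1000),
              class = "st_spectrum")
  }
  # constant spectrum: nothing
  expect_identical(nrow(spectrum_local_maxima(mk(matrix(1, 3, 6)))), 0L)
  # canonical row: maxima at the 2nd and 4th samples
  m <- spectrum_local_maxima(mk(matrix(c(0, 1, 0, 2, 0), 1)))
  expect_equal(m$time_index, c(2L, 4L))
  # plateau reported once, leftmost; boundary plateaus excluded
  m2 <- spectrum_local_maxima(mk(matrix(c(0, 2, 2, 1, 3, 0), 1)))
  expect_equal(m2$time_index, c(2L, 5L))
  m3 <- spectrum_local_maxima(mk(matrix(c(2, 2, 1, 0, 1, 1), 1)))
  expect_identical(nrow(m3), 0L)
  # frequency direction: same rule down the columns
  mf <- spectrum_local_maxima(mk(matrix(c(0, 1, 0, 2, 0), 5, 1)),
                              along = "frequency")
  expect_equal(mf$freq_index, c(2L, 4L))
})
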