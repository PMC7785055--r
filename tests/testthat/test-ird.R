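test_that("pressure normalization is the expected affine map", {
  expect_equal(normalize_pressure(hs_signal(c(2, 4, 6), 3))$samples,
               c(0, 0.5, 1))
  unit <- hs_signal(c(0, 0.3, 1, 0.2), 4)
  expect_equal(normalize_pressure(unit)$samples, unit$samples)
  neg <- normalize_pressure(hs_signal(-c(2, 4, 6), 3))
  expect_equal(neg$samples, 1 - c(0, 0.5, 1))
  expect_error(normalize_pressure(hs_signal(rep(1, 10), 10)), "constant")
})

test_that("downslope extraction follows the peak-to-threshold rule", {
  # symmetric triangle peaking at index 50, crossing 0.1 on the way down
  x <- c(seq(0, 1, length.out = 50), seq(1, 0, length.out = 50))
  win <- extract_downslope(hs_signal(x, 100))
  expect_equal(unname(win[1]), 50)
  expect_equal(unname(win[2]), 50 + which(x[50:99] < 0.1)[1] - 1)

  # rise with no fall: the threshold is never crossed, end = last sample
  rise <- hs_signal(c(seq(0, 1, length.out = 60), rep(1, 20)), 100)
  win2 <- extract_downslope(rise)
  expect_equal(unname(win2[1]), 60)
  expect_equal(unname(win2[2]), 80)

  # two equal maxima: the earlier wins
  two <- c(seq(0, 1, length.out = 30), seq(1, 0.5, length.out = 20),
           seq(0.5, 1, length.out = 20), seq(1, 0, length.out = 30))
  win3 <- extract_downslope(hs_signal(two, 100))
  expect_equal(unname(win3[1]), 30)

  short <- hs_signal(c(seq(0, 1, length.out = 95), seq(1, 0, length.out = 5)),
                     100)
  expect_error(extract_downslope(short), "downslope too short")
})

test_that("a pure delay between identical beats is recovered exactly", {
  lv <- make_pressure_beat()
  rv <- make_pressure_beat(amp = 25, base = 3, shift_ms = 15)
  res <- compute_ird(lv, rv)
  expect_equal(res$ird_ms, 15, tolerance = 1 + 1e-8)
  expect_gt(res$peak_r, 0.99)

  same <- compute_ird(lv, lv)
  expect_equal(same$ird_ms, 0)
  expect_equal(same$peak_r, 1)
})

test_that("programmed offsets from -30 to 30 ms are recovered within one sample", {
  lv <- make_pressure_beat()
  for (off in seq(-30, 30, by = 10)) {
    rv <- make_pressure_beat(amp = 22, base = 3, shift_ms = off)
    expect_equal(compute_ird(lv, rv)$ird_ms, off, tolerance = 1 + 1e-8)
  }
})

test_that("IRD is antisymmetric, shift-equivariant and amplitude-invariant", {
  lv <- make_pressure_beat()
  rv <- make_pressure_beat(amp = 22, base = 3, shift_ms = -20)
  fwd <- compute_ird(lv, rv)
  bwd <- compute_ird(rv, lv)
  expect_lte(abs(fwd$ird_ms + bwd$ird_ms), 1)

  rv_later <- make_pressure_beat(amp = 22, base = 3, shift_ms = -20 + 12)
  shifted <- compute_ird(lv, rv_later)
  expect_equal(shifted$ird_ms - fwd$ird_ms, 12, tolerance = 1 + 1e-8)
  expect_equal(shifted$peak_r, fwd$peak_r, tolerance = 1e-6)

  scaled <- compute_ird(hs_signal(3.7 * lv$samples, lv$fs),
                        hs_signal(0.4 * rv$samples, rv$fs))
  expect_equal(scaled$ird_ms, fwd$ird_ms)
})

test_that("noisy downslope offsets are recovered without bias", {
  offs <- numeric(50)
  for (seed in 1:50) {
    noisy <- s2split:::with_seed(seed, {
      lv <- make_pressure_beat()
      rv <- make_pressure_beat(amp = 22, base = 3, shift_ms = -20)
      p_lv <- mean((lv$samples - mean(lv$samples))^2)
      p_rv <- mean((rv$samples - mean(rv$samples))^2)
      list(lv = hs_signal(lv$samples + rnorm(700, sd = sqrt(p_lv / 100)),
                          1000),
           rv = hs_signal(rv$samples + rnorm(700, sd = sqrt(p_rv / 100)),
                          1000))
    })
    offs[seed] <- compute_ird(noisy$lv, noisy$rv)$ird_ms
  }
  expect_lt(abs(mean(offs) - (-20)), 2)
})

test_that("the correlation curve is complete and consistent", {
  lv <- make_pressure_beat()
  rv <- make_pressure_beat(amp = 22, base = 3, shift_ms = 8)
  res <- compute_ird(lv, rv, max_lag_ms = 40)
  expect_true(all(abs(res$corr_curve$lag_ms) <= 40))
  expect_equal(max(res$corr_curve$r), res$peak_r)
  expect_equal(res$corr_curve$lag_ms[which.max(res$corr_curve$r)],
               res$ird_ms)
})
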