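test_that("the component envelope vanishes at both ends and peaks where it should", {
  env <- s2split:::s2_envelope
  expect_equal(env(0), 0)
  expect_equal(env(60), 0, tolerance = 1e-12)
  # dense grid search over the printed envelope as the oracle
  tg <- seq(0, 60, by = 0.01)
  vals <- env(tg)
  t_peak <- tg[which.max(vals)]
  v_peak <- max(vals)
  samp <- simulate_component("A2", fs = 10000)
  # the sampled waveform can never exceed the envelope maximum, and its
  # envelope (abs) approaches it somewhere near the oracle peak
  expect_lt(max(abs(samp$samples)), v_peak + 1e-12)
  expect_equal(env(t_peak), v_peak)
  expect_gt(t_peak, 5); expect_lt(t_peak, 30)
})

test_that("instantaneous frequency laws start at the printed onset values and decrease", {
  f_a <- s2split:::chirp_frequency(0, "A2")
  f_p <- s2split:::chirp_frequency(0, "P2")
  expect_equal(f_a, 451.4)
  expect_equal(f_p, 356.3)
  tg <- seq(0, 60, by = 0.5)
  expect_true(all(diff(s2split:::chirp_frequency(tg, "A2")) < 0))
  expect_true(all(diff(s2split:::chirp_frequency(tg, "P2")) < 0))
  # A2 stays above P2 throughout
  expect_true(all(s2split:::chirp_frequency(tg, "A2") >
                    s2split:::chirp_frequency(tg, "P2")))
})

test_that("S2 is the additive superposition of its delayed components", {
  s <- simulate_s2(s2_sim_spec(25, amp_a = 0))
  p2 <- simulate_component("P2")
  expect_equal(s$samples, c(rep(0, 25), p2$samples))

  s0 <- simulate_s2(0)
  expect_length(s0, 61L)
  a2 <- simulate_component("A2")
  expect_equal(s0$samples, a2$samples + p2$samples)

  # doubling the A2 amplitude doubles exactly the A2 part
  s1 <- simulate_s2(s2_sim_spec(30, amp_a = 1))
  s2 <- simulate_s2(s2_sim_spec(30, amp_a = 2))
  expect_equal(s2$samples - s1$samples, attr(s1, "parts")$a2,
               tolerance = 1e-12)
})

test_that("additive noise realises the requested SNR and is reproducible", {
  s <- simulate_s2(s2_sim_spec(30, snr_db = 20, seed = 11))
  parts <- attr(s, "parts")
  clean <- parts$a2 + parts$p2
  snr_emp <- 10 * log10(mean(clean^2) / mean(parts$noise^2))
  expect_gt(snr_emp, 19); expect_lt(snr_emp, 21)

  s_again <- simulate_s2(s2_sim_spec(30, snr_db = 20, seed = 11))
  expect_identical(s$samples, s_again$samples)
  expect_error(s2_sim_spec(30, snr_db = 20), "seed")

  # the caller's RNG stream is not consumed
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(simulate_s2(s2_sim_spec(30, snr_db = 10, seed = 5)))
  expect_identical(rnorm(1), before)
})

test_that("lone components produce ridges whose median frequencies order as A2 above P2", {
  med_ridge_freq <- function(which) {
    ts <- hs_signal(simulate_component(which)$samples, 1000)
    r <- find_ridges(stransform(highpass(ts, 50), 50, 250, 1,
                                window_factor = 1.5))
    median(r[[1]]$points$freq_hz)
  }
  expect_gt(med_ridge_freq("A2"), med_ridge_freq("P2"))
})
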