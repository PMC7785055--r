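# hand-built ridge with constant time per frequency row
fake_ridge <- function(freqs, times, amps = 1, rank = NA_integer_) {
  pts <- data.frame(freq_hz = freqs, time_ms = rep_len(times, length(freqs)),
                    amp = rep_len(amps, length(freqs)))
  structure(list(points = pts, weight = sum(pts$amp * pts$freq_hz),
                 norm_weight = NA_real_, rank = rank),
            class = "st_ridge")
}

test_that("splitting_interval reduces to the median offset of common rows", {
  r1 <- fake_ridge(51:150, times = 20, amps = 2, rank = 1L)
  r2 <- fake_ridge(51:150, times = 50, amps = 1, rank = 2L)
  res <- splitting_interval(list(r1, r2))
  expect_equal(res$status, "ok")
  expect_equal(res$interval_ms, 30)
  expect_equal(res$n_common_freqs, 100L)
  # earlier-median ridge is reported first; signed deltas are positive
  expect_equal(median(res$ridge_a$points$time_ms), 20)
  expect_true(all(res$per_freq_deltas$delta_ms == 30))
})

test_that("the median of an even number of offsets is the mean of the central pair", {
  t1 <- rep(10, 4)
  t2 <- c(20, 24, 31, 45)   # |deltas| 10,14,21,35 -> median 17.5
  r1 <- structure(list(points = data.frame(freq_hz = 51:54, time_ms = t1,
                                           amp = 1),
                       weight = 10, norm_weight = 1, rank = 1L),
                  class = "st_ridge")
  r2 <- structure(list(points = data.frame(freq_hz = 51:54, time_ms = t2,
                                           amp = 1),
                       weight = 5, norm_weight = 0.5, rank = 2L),
                  class = "st_ridge")
  res <- splitting_interval(list(r1, r2), min_common = 4)
  expect_equal(res$interval_ms, 17.5)
})

test_that("degenerate ridge sets yield status codes, not numbers", {
  res1 <- splitting_interval(list(fake_ridge(51:150, 20, rank = 1L)))
  expect_equal(res1$status, "too_few_ridges")
  expect_true(is.na(res1$interval_ms))

  r1 <- fake_ridge(51:150, 20, rank = 1L)
  r2 <- fake_ridge(160:200, 50, rank = 2L)  # no shared rows
  res2 <- splitting_interval(list(r1, r2))
  expect_equal(res2$status, "no_common_frequencies")
  expect_true(is.na(res2$interval_ms))
})

test_that("a constant spectrum has no ridges", {
  spec <- structure(list(amplitudes = matrix(1, 201, 90), freqs = 50:250,
                         times_ms = 0:89, fs = 1000),
                    class = "st_spectrum")
  expect_length(find_ridges(spec), 0L)
})

test_that("a simulated S2 yields at least two band-spanning ridges", {
  s2 <- simulate_s2(30)
  spec <- stransform(highpass(s2, 50), 50, 250, 1, window_factor = 1.5)
  ridges <- find_ridges(spec)
  expect_gte(length(ridges), 2L)
  spans <- vapply(ridges, function(r) diff(range(r$points$freq_hz)),
                  numeric(1))
  expect_true(all(spans > 50))
  expect_equal(ridges[[1]]$norm_weight, 1)
  expect_equal(vapply(ridges, `[[`, integer(1), "rank"),
               seq_along(ridges))
})

test_that("a lone aortic component yields one dominant ridge", {
  a2 <- hs_signal(simulate_component("A2")$samples, 1000)
  ridges <- find_ridges(stransform(highpass(a2, 50), 50, 250, 1,
                                   window_factor = 1.5))
  expect_gte(length(ridges), 1L)
  expect_gt(diff(range(ridges[[1]]$points$freq_hz)), 50)
  if (length(ridges) > 1L) {
    expect_lt(ridges[[2]]$norm_weight, 0.5)
  }
})

test_that("splitting estimates match the programmed split across its range", {
  for (sp in c(10, 40, 70)) {
    res <- estimate_splitting(simulate_s2(sp))
    expect_equal(res$status, "ok")
    expect_lt(abs(res$interval_ms - sp), 5)
  }
})

test_that("the estimate is exactly invariant to amplitude scaling", {
  s2 <- simulate_s2(35)
  r1 <- estimate_splitting(s2)
  r2 <- estimate_splitting(hs_signal(137.5 * s2$samples, s2$fs))
  expect_identical(r1$interval_ms, r2$interval_ms)
  expect_identical(r1$status, r2$status)
})

test_that("prepending silence shifts ridges but not the interval", {
  s2 <- simulate_s2(40)
  pad <- hs_signal(c(rep(0, 25), s2$samples), s2$fs)
  r0 <- estimate_splitting(s2)
  r1 <- estimate_splitting(pad)
  expect_equal(r1$interval_ms, r0$interval_ms, tolerance = 1 + 1e-8)
  expect_equal(median(r1$ridge_a$points$time_ms),
               median(r0$ridge_a$points$time_ms) + 25,
               tolerance = 2)
})

test_that("swapping the component amplitudes barely moves the estimate", {
  a <- estimate_splitting(simulate_s2(s2_sim_spec(30, amp_a = 2, amp_p = 1)))
  b <- estimate_splitting(simulate_s2(s2_sim_spec(30, amp_a = 1, amp_p = 2)))
  expect_equal(a$status, "ok")
  expect_equal(b$status, "ok")
  expect_lte(abs(a$interval_ms - b$interval_ms), 2)
})

test_that("estimates increase strictly with the true split", {
  est <- vapply(seq(10, 70, by = 10), function(sp) {
    estimate_splitting(simulate_s2(sp))$interval_ms
  }, numeric(1))
  expect_true(all(diff(est) > 0))
})

test_that("low-amplitude noise snippets are rejected rather than scored", {
  n_ok <- 0L
  for (seed in 1:50) {
    noise <- s2split:::with_seed(seed, rnorm(100, sd = 0.01))
    res <- estimate_splitting(hs_signal(noise, 1000))
    if (res$status == "ok") n_ok <- n_ok + 1L
  }
  expect_lte(n_ok, 10L)  # >= 80% must carry a failure status
})
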