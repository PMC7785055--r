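#' @name sweeps
#' @title Simulation validation sweeps
#'
#' @description
#' The three accuracy sweeps that characterise the splitting estimator on
#' simulated second heart sounds: across true splitting intervals
#' (noiseless), across A2/P2 amplitude ratios (noiseless, split fixed at
#' 30 ms), and across signal-to-noise ratios (split fixed at 30 ms).
#' Every sweep returns the per-condition row table plus summary
#' statistics; the summaries are computed over rows with status `"ok"`
#' and the number of rows without an estimate is reported alongside
#' (`n_failed`) -- the estimator abstains rather than guesses when no
#' credible ridge pair exists.
#'
#' @param splits vector of true splitting intervals in ms.
#' @param ratios vector of A2 amplitudes (P2 amplitude fixed at 1).
#' @param snr_db vector of SNR levels in dB.
#' @param split_ms fixed true split for the amplitude and SNR sweeps.
#' @param n_seeds noise realisations per SNR level (default 1).
#' @param seed base seed; per-row seeds are derived deterministically.
#' @param fs simulator sampling rate in Hz.
#' @param config a [start_config()].
#' @return A list of class `sweep_result` with elements `rows` (data
#'   frame: `condition`, `true_split_ms`, `amp_a`, `snr_db`, `seed`,
#'   `est_split_ms`, `error_ms`, `status`) and `summary` (named list,
#'   see each function).
NULL

sweep_row <- function(condition, true_split, amp_a, snr_db, seed, res) {
  est <- if (res$status == "ok") res$interval_ms else NA_real_
  data.frame(condition = condition, true_split_ms = true_split,
             amp_a = amp_a, snr_db = if (is.null(snr_db)) NA_real_ else snr_db,
             seed = if (is.null(seed)) NA_integer_ else seed,
             est_split_ms = est, error_ms = est - true_split,
             status = res$status)
}

#' @rdname sweeps
#' @details `sweep_intervals()` runs noiseless simulations with
#'   `amp_a = amp_p = 1` over `splits` (default 10-70 ms in 1 ms steps).
#'   Its summary reports the signed mean error, mean absolute error,
#'   RMSE, maximum absolute error, and the Pearson correlation and R^2
#'   between estimated and true splits.
#' @export
sweep_intervals <- function(splits = seq(10, 70, by = 1), fs = 1000,
                            config = start_config()) {
  rows <- do.call(rbind, lapply(splits, function(sp) {
    s2 <- simulate_s2(s2_sim_spec(sp, fs = fs))
    sweep_row("interval", attr(s2, "truth_split_ms"), 1, NULL, NULL,
              estimate_splitting(s2, config))
  }))
  ok <- rows$status == "ok"
  r <- if (sum(ok) >= 3L) {
    stats::cor(rows$true_split_ms[ok], rows$est_split_ms[ok])
  } else NA_real_
  structure(list(rows = rows, summary = list(
    n = nrow(rows), n_failed = sum(!ok),
    mean_error = mean(rows$error_ms[ok]),
    mean_abs_error = mean(abs(rows$error_ms[ok])),
    rmse = sqrt(mean(rows$error_ms[ok]^2)),
    max_abs_error = max(abs(rows$error_ms[ok])),
    pearson_r = r, r_squared = r^2)),
    class = "sweep_result")
}

#' @rdname sweeps
#' @details `sweep_amplitude()` varies the A2 amplitude over `ratios`
#'   (default 0.2-5.0 in 0.2 steps) at a fixed noiseless split. Its
#'   summary reports the maximum absolute error, the spread (max - min)
#'   of estimates over ratios at or below 4, and the shift of the
#'   estimate at the largest ratio relative to the mean estimate over
#'   ratios at or below 4.
#' @export
sweep_amplitude <- function(ratios = seq(0.2, 5, by = 0.2), split_ms = 30,
                            fs = 1000, config = start_config()) {
  rows <- do.call(rbind, lapply(ratios, function(a) {
    s2 <- simulate_s2(s2_sim_spec(split_ms, amp_a = a, fs = fs))
    sweep_row("amp_ratio", attr(s2, "truth_split_ms"), a, NULL, NULL,
              estimate_splitting(s2, config))
  }))
  ok <- rows$status == "ok"
  low <- ok & rows$amp_a <= 4
  est_top <- rows$est_split_ms[ok & rows$amp_a == max(ratios)]
  structure(list(rows = rows, summary = list(
    n = nrow(rows), n_failed = sum(!ok),
    max_abs_error = max(abs(rows$error_ms[ok])),
    spread_le4 = diff(range(rows$est_split_ms[low])),
    shift_at_max_ratio = if (length(est_top)) {
      est_top - mean(rows$est_split_ms[low])
    } else NA_real_)),
    class = "sweep_result")
}

#' @rdname sweeps
#' @details `sweep_snr()` adds seeded white Gaussian noise at each level
#'   of `snr_db` (default 10-30 dB in 1 dB steps), `n_seeds` realisations
#'   per level, at a fixed split with `amp_a = amp_p = 1`. Its summary
#'   reports the maximum and mean absolute error over successful rows
#'   and a per-SNR table of mean errors and failure counts.
#' @export
sweep_snr <- function(snr_db = seq(10, 30, by = 1), split_ms = 30,
                      n_seeds = 1, seed = 1, fs = 1000,
                      config = start_config()) {
  grid <- expand.grid(snr = snr_db, rep = seq_len(n_seeds))
  rows <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    s <- grid$snr[i]
    row_seed <- as.integer((seed + 7919 * grid$rep[i] + 131 * s) %% .Machine$integer.max)
    s2 <- simulate_s2(s2_sim_spec(split_ms, snr_db = s, fs = fs,
                                  seed = row_seed))
    sweep_row("snr", attr(s2, "truth_split_ms"), 1, s, row_seed,
              estimate_splitting(s2, config))
  }))
  ok <- rows$status == "ok"
  per_snr <- do.call(rbind, lapply(sort(unique(rows$snr_db)), function(s) {
    sel <- rows$snr_db == s & ok
    data.frame(snr_db = s, n_ok = sum(sel),
               n_failed = sum(rows$snr_db == s & !ok),
               mean_error = if (any(sel)) mean(rows$error_ms[sel]) else NA_real_,
               mean_abs_error = if (any(sel)) mean(abs(rows$error_ms[sel])) else NA_real_)
  }))
  structure(list(rows = rows, summary = list(
    n = nrow(rows), n_failed = sum(!ok),
    max_abs_error = if (any(ok)) max(abs(rows$error_ms[ok])) else NA_real_,
    mean_abs_error = if (any(ok)) mean(abs(rows$error_ms[ok])) else NA_real_,
    per_snr = per_snr)),
    class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<sweep_result> %s: %d rows (%d without estimate)\n",
              x$rows$condition[1L], s$n, s$n_failed))
  for (nm in setdiff(names(s), c("n", "n_failed", "per_snr"))) {
    if (length(s[[nm]]) == 1L) cat(sprintf("  %s: %.4g\n", nm, s[[nm]]))
  }
  invisible(x)
}
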