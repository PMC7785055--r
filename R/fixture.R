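#' Generate a synthetic multi-channel recording with known ground truth
#'
#' Builds a complete, time-aligned test recording -- ECG, heart-sound
#' channel and LV/RV pressures -- from programmed per-beat parameters,
#' so the whole analysis pipeline can be exercised and scored without
#' any real data. Per beat it places:
#' \itemize{
#'   \item an impulse-like R complex (narrow Gaussian) on the ECG;
#'   \item an S1 burst (band-limited noise packet under a raised-cosine
#'     envelope) 30 ms after R and a simulated S2 (see [simulate_s2()])
#'     320 ms after R on the sound channel;
#'   \item smooth pressure beats (raised-cosine rise, exponential
#'     relaxation fall), with the RV downslope delayed by `ird_ms`
#'     relative to the LV downslope (positive IRD = LV earlier).
#' }
#' Premature beats are emulated by shifting the R complex of each listed
#' beat 35% of an RR interval earlier. White Gaussian channel noise is
#' added at `snr_db` relative to each channel's own power.
#'
#' @param n_beats number of beats (default 20).
#' @param bpm heart rate in beats per minute (default 70).
#' @param split_ms programmed A2-P2 splitting interval in ms; a scalar
#'   or one value per beat (default 40).
#' @param ird_ms programmed interventricular relaxation delay in ms,
#'   scalar or per beat (default 8).
#' @param snr_db channel signal-to-noise ratio in dB, or `NULL` for
#'   noiseless channels (default 20).
#' @param pvc_positions integer beat indices turned into premature beats
#'   (default none).
#' @param fs sampling rate in Hz (default 1000).
#' @param seed integer seed; the bundle is reproducible byte-for-byte.
#' @return A [recording_bundle()] with attribute `truth`, a data frame
#'   with one row per beat: `beat`, `r_index` (true R sample),
#'   `split_ms` (as realised on the sample grid), `ird_ms`, `pvc`.
#' @examples
#' fx <- make_fixture_recording(n_beats = 8, seed = 1)
#' attr(fx, "truth")
#' @export
make_fixture_recording <- function(n_beats = 20, bpm = 70, split_ms = 40,
                                   ird_ms = 8, snr_db = 20,
                                   pvc_positions = integer(0), fs = 1000,
                                   seed = 1) {
  stopifnot(n_beats >= 1, bpm > 20, fs >= 500)
  split_ms <- rep_len(split_ms, n_beats)
  ird_ms <- rep_len(ird_ms, n_beats)
  rr <- as.integer(round(60000 / bpm * fs / 1000))
  lead_in <- as.integer(round(0.5 * fs))
  r_true <- lead_in + (seq_len(n_beats) - 1L) * rr
  pvc <- seq_len(n_beats) %in% pvc_positions
  r_true[pvc] <- r_true[pvc] - as.integer(round(0.35 * rr))
  n <- r_true[n_beats] + rr

  ms <- function(v) as.integer(round(v * fs / 1000))
  tgrid_ms <- function(len) (seq_len(len) - 1L) * 1000 / fs

  with_seed(seed, {
    # --- ECG: narrow Gaussian R complexes ------------------------------
    ecg <- numeric(n)
    qrs_len <- ms(40)
    qrs_t <- tgrid_ms(qrs_len) - 20
    qrs <- exp(-(qrs_t / 4)^2)
    for (r in r_true) {
      i0 <- r - ms(20)
      idx <- seq.int(i0, i0 + qrs_len - 1L)
      keep <- idx >= 1L & idx <= n
      ecg[idx[keep]] <- ecg[idx[keep]] + qrs[keep]
    }

    # --- sound: S1 noise packets + simulated S2 ------------------------
    sound <- numeric(n)
    s1_len <- ms(60)
    s1_env <- 0.5 * (1 - cos(2 * pi * seq_len(s1_len) / (s1_len + 1L)))
    # one S1 waveform per recording: S1 morphology repeats beat to beat,
    # which is what makes the median-beat template a usable reference
    s1 <- bandpass(hs_signal(stats::rnorm(s1_len), fs), 50, 250,
                   order = 2L)$samples * s1_env
    s1 <- 0.6 * s1 / max(abs(s1))
    for (k in seq_len(n_beats)) {
      i0 <- r_true[k] + ms(30)
      sound[i0:(i0 + s1_len - 1L)] <- sound[i0:(i0 + s1_len - 1L)] + s1
      s2 <- simulate_s2(s2_sim_spec(split_ms[k], fs = fs))
      j0 <- r_true[k] + ms(320)
      j1 <- j0 + length(s2$samples) - 1L
      sound[j0:j1] <- sound[j0:j1] + s2$samples
    }

    # --- pressures: raised-cosine rise, exponential fall ---------------
    beat_pressure <- function(t_ms, rise_start, rise_len, fall_tau) {
      s <- numeric(length(t_ms))
      ris <- t_ms >= rise_start & t_ms < rise_start + rise_len
      s[ris] <- 0.5 * (1 - cos(pi * (t_ms[ris] - rise_start) / rise_len))
      fall <- t_ms >= rise_start + rise_len
      s[fall] <- exp(-(t_ms[fall] - rise_start - rise_len) / fall_tau)
      s
    }
    lvp <- numeric(n) + 8
    rvp <- numeric(n) + 3
    beat_len <- min(rr, ms(700))
    bt <- tgrid_ms(beat_len)
    for (k in seq_len(n_beats)) {
      idx <- r_true[k]:(r_true[k] + beat_len - 1L)
      lvp[idx] <- lvp[idx] + 90 * beat_pressure(bt, 50, 180, 50)
      # positive IRD: LV downslope earlier, so RV rise/fall shifted later
      rvp[idx] <- rvp[idx] + 22 * beat_pressure(bt, 50 + ird_ms[k], 180, 50)
    }

    add_noise <- function(x) {
      if (is.null(snr_db)) return(x)
      p <- mean((x - mean(x))^2)
      x + stats::rnorm(length(x), sd = sqrt(p / 10^(snr_db / 10)))
    }
    ecg <- add_noise(ecg)
    sound <- add_noise(sound)
    lvp <- add_noise(lvp)
    rvp <- add_noise(rvp)

    bundle <- recording_bundle(
      ecg = hs_signal(ecg, fs, units = "mV"),
      sound = hs_signal(sound, fs, units = "a.u."),
      lvp = hs_signal(lvp, fs, units = "mmHg"),
      rvp = hs_signal(rvp, fs, units = "mmHg"))
    attr(bundle, "truth") <- data.frame(
      beat = seq_len(n_beats), r_index = r_true,
      split_ms = ms(split_ms) * 1000 / fs, ird_ms = ird_ms, pvc = pvc)
    bundle
  })
}
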