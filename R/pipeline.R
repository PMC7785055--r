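#' Configuration for the recording pipeline
#'
#' Bundles the thresholds that turn a raw multi-channel recording into
#' per-beat results. Defaults mirror the processing conventions described
#' in the methods vignette; each is configurable.
#'
#' @param start a [start_config()] for the splitting estimator.
#' @param r_band ECG bandpass for R-peak detection, Hz (default 10-40).
#' @param r_threshold fraction of the rolling 2-s maximum of the squared,
#'   band-passed ECG used as detection threshold (default 0.4).
#' @param r_refractory_ms refractory period between R detections
#'   (default 200).
#' @param pvc_rr_frac a beat whose RR interval to the previous beat is
#'   below this fraction of the median RR is flagged as a premature
#'   ventricular contraction (default 0.8).
#' @param noisy_r beats whose correlation with the median-beat template
#'   falls below this value are flagged noisy (default 0.8).
#' @param s1_ms length of the S1 window after the R peak (default 120).
#' @param s2_search_start_ms start of the S2 search window after R
#'   (default 200).
#' @param s2_search_rr_frac end of the S2 search window as a fraction of
#'   the beat's RR interval (default 0.6).
#' @param s2_pad_ms padding added on both sides of the detected S2 burst
#'   (default 40).
#' @param sound_band displacement bandpass in Hz (default 50-250).
#' @param integration_highpass_hz drift-removal highpass applied after
#'   each integration pass (default 2).
#' @param ird_max_lag_ms lag search half-width for [compute_ird()]
#'   (default 100).
#' @param pressure_window_ms length of the per-beat pressure window used
#'   for IRD (default 700, capped at the beat's RR).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(start = start_config(),
                            r_band = c(10, 40), r_threshold = 0.4,
                            r_refractory_ms = 200, pvc_rr_frac = 0.8,
                            noisy_r = 0.8, s1_ms = 120,
                            s2_search_start_ms = 200,
                            s2_search_rr_frac = 0.6, s2_pad_ms = 40,
                            sound_band = c(50, 250),
                            integration_highpass_hz = 2,
                            ird_max_lag_ms = 100,
                            pressure_window_ms = 700) {
  stopifnot(inherits(start, "start_config"), length(r_band) == 2L,
            r_threshold > 0, r_threshold < 1, r_refractory_ms > 0,
            pvc_rr_frac > 0, pvc_rr_frac < 1, noisy_r > -1, noisy_r < 1,
            length(sound_band) == 2L)
  structure(list(start = start, r_band = r_band, r_threshold = r_threshold,
                 r_refractory_ms = r_refractory_ms,
                 pvc_rr_frac = pvc_rr_frac, noisy_r = noisy_r,
                 s1_ms = s1_ms, s2_search_start_ms = s2_search_start_ms,
                 s2_search_rr_frac = s2_search_rr_frac,
                 s2_pad_ms = s2_pad_ms, sound_band = sound_band,
                 integration_highpass_hz = integration_highpass_hz,
                 ird_max_lag_ms = ird_max_lag_ms,
                 pressure_window_ms = pressure_window_ms),
            class = "pipeline_config")
}

#' Time-aligned multi-channel recording
#'
#' Container for the channels of one recording: a heart-sound signal
#' (either a pre-combined channel or raw triaxial accelerometer axes),
#' an ECG lead for beat timing, and optional LV/RV pressures. All
#' channels must share one sampling rate and be time-aligned; alignment
#' against a synchronisation pulse is assumed to have happened upstream.
#'
#' @param ecg `hs_signal` ECG lead.
#' @param sound optional combined heart-sound/acceleration channel.
#' @param sound_x,sound_y,sound_z optional raw accelerometer axes (used
#'   when `sound` is absent).
#' @param lvp,rvp optional LV and RV pressure channels.
#' @return An object of class `recording_bundle`.
#' @export
recording_bundle <- function(ecg, sound = NULL, sound_x = NULL,
                             sound_y = NULL, sound_z = NULL,
                             lvp = NULL, rvp = NULL) {
  assert_hs_signal(ecg)
  chans <- Filter(Negate(is.null),
                  list(sound = sound, sound_x = sound_x, sound_y = sound_y,
                       sound_z = sound_z, lvp = lvp, rvp = rvp))
  if (is.null(sound) && (is.null(sound_x) || is.null(sound_y) ||
                         is.null(sound_z))) {
    stop("provide either a combined 'sound' channel or all three axes")
  }
  for (nm in names(chans)) {
    assert_hs_signal(chans[[nm]], nm)
    if (chans[[nm]]$fs != ecg$fs) {
      stop(sprintf("channel '%s' sampling rate differs from the ECG", nm))
    }
  }
  structure(list(ecg = ecg, sound = sound, sound_x = sound_x,
                 sound_y = sound_y, sound_z = sound_z,
                 lvp = lvp, rvp = rvp, fs = ecg$fs),
            class = "recording_bundle")
}

#' @export
print.recording_bundle <- function(x, ...) {
  have <- names(Filter(Negate(is.null),
                       x[c("sound", "sound_x", "sound_y", "sound_z",
                           "lvp", "rvp")]))
  cat(sprintf("<recording_bundle> %.1f s @ %g Hz; channels: ecg, %s\n",
              signal_duration(x$ecg), x$fs, paste(have, collapse = ", ")))
  invisible(x)
}

#' Combine triaxial accelerometer axes
#'
#' Forms a single motion-magnitude channel as the per-sample Euclidean
#' norm of the mean-removed X, Y and Z axes. Removing each axis mean
#' discards the gravity/offset component, so constant axes contribute
#' nothing.
#'
#' @param x,y,z `hs_signal` axes with equal length and sampling rate.
#' @return An `hs_signal` of non-negative magnitudes.
#' @export
combine_accelerometer <- function(x, y, z) {
  assert_hs_signal(x); assert_hs_signal(y); assert_hs_signal(z)
  if (length(x$samples) != length(y$samples) ||
      length(y$samples) != length(z$samples)) {
    stop("axes must have equal lengths")
  }
  if (x$fs != y$fs || y$fs != z$fs) stop("axes must share one sampling rate")
  xt <- x$samples - mean(x$samples)
  yt <- y$samples - mean(y$samples)
  zt <- z$samples - mean(z$samples)
  hs_signal(sqrt(xt^2 + yt^2 + zt^2), x$fs,
            start_time = x$start_time, units = x$units)
}

# cumulative trapezoidal integral with respect to time
cumtrapz_ts <- function(x, fs) {
  n <- length(x)
  c(0, cumsum((x[-1L] + x[-n]) / 2)) / fs
}

#' Displacement from an acceleration signal
#'
#' Integrates an acceleration-like signal twice (cumulative trapezoidal
#' rule), applying a zero-phase 2 Hz second-order highpass after each
#' pass to suppress the unbounded drift that plain double integration
#' accumulates. A sinusoid at frequency f comes out scaled by
#' `(2*pi*f)^-2` with its phase preserved.
#'
#' @param ts an `hs_signal` acceleration trace.
#' @param drift_highpass_hz drift-removal cutoff (default 2 Hz).
#' @return An `hs_signal` displacement trace of the same length.
#' @export
displacement <- function(ts, drift_highpass_hz = 2) {
  assert_hs_signal(ts)
  out <- ts
  for (pass in 1:2) {
    out <- hs_signal(cumtrapz_ts(out$samples, out$fs), out$fs,
                     start_time = ts$start_time, units = ts$units)
    if (stats::sd(out$samples) > 0) {
      out <- highpass(out, drift_highpass_hz, order = 2L)
    }
  }
  out
}

# piecewise rolling maximum: max over the blocks within half_window of
# each 0.5-s block (coarse approximation of a sliding 2-s maximum)
block_rolling_max <- function(x, fs, window_s = 2) {
  block <- max(1L, as.integer(round(fs / 2)))
  n_blocks <- ceiling(length(x) / block)
  bmax <- vapply(seq_len(n_blocks), function(b) {
    i0 <- (b - 1L) * block + 1L
    max(x[i0:min(b * block, length(x))])
  }, numeric(1))
  half <- max(1L, as.integer(round(window_s * fs / block / 2)))
  smax <- vapply(seq_len(n_blocks), function(b) {
    max(bmax[max(1L, b - half):min(n_blocks, b + half)])
  }, numeric(1))
  rep(smax, each = block, length.out = length(x))
}

#' Detect R peaks in an ECG lead
#'
#' Band-passes the ECG to the QRS band (10-40 Hz), squares it, and picks
#' local maxima exceeding an adaptive threshold (a fraction of the
#' rolling 2-s maximum), enforcing a refractory period by keeping the
#' strongest candidate within each refractory window.
#'
#' @param ecg an `hs_signal` ECG lead with visible R waves.
#' @param threshold fraction of the rolling maximum (default 0.4).
#' @param refractory_ms refractory period in ms (default 200).
#' @param band QRS bandpass in Hz (default `c(10, 40)`).
#' @return Integer vector of R-peak sample indices, ascending; errors if
#'   nothing is detected.
#' @export
detect_r_peaks <- function(ecg, threshold = 0.4, refractory_ms = 200,
                           band = c(10, 40)) {
  assert_hs_signal(ecg)
  fs <- ecg$fs
  sq <- bandpass(ecg, band[1L], band[2L], order = 2L)$samples^2
  if (max(sq) <= 0) stop("no R peaks detected (flat ECG)")
  thr <- threshold * block_rolling_max(sq, fs)
  cand <- row_local_maxima(sq)
  cand <- cand[sq[cand] > thr[cand]]
  if (!length(cand)) stop("no R peaks detected above threshold")
  refr <- as.integer(round(refractory_ms * fs / 1000))
  keep <- logical(length(cand))
  ord <- order(-sq[cand])          # strongest first
  blocked <- rep(FALSE, length(cand))
  for (j in ord) {
    if (blocked[j]) next
    keep[j] <- TRUE
    blocked[abs(cand - cand[j]) <= refr] <- TRUE
  }
  sort(cand[keep])
}

# combined sound -> displacement -> sound-band bandpass
process_sound <- function(bundle, config) {
  snd <- bundle$sound
  if (is.null(snd)) {
    snd <- combine_accelerometer(bundle$sound_x, bundle$sound_y,
                                 bundle$sound_z)
  }
  disp <- displacement(snd, drift_highpass_hz = config$integration_highpass_hz)
  bandpass(disp, config$sound_band[1L], config$sound_band[2L], order = 2L)
}

#' Segment a recording into beats
#'
#' Aligns beats on their R peaks, builds a median-beat template of the
#' processed heart-sound signal, grades every beat against it, and
#' assigns per-beat windows and quality flags:
#' \itemize{
#'   \item `pvc` -- RR interval to the previous beat below
#'     `pvc_rr_frac` of the median RR;
#'   \item `post_pvc` -- one of the two beats following a `pvc` beat;
#'   \item `noisy` -- template correlation below `noisy_r`;
#'   \item `accepted` -- none of the above.
#' }
#' The S1 window spans the first `s1_ms` after R; the S2 window is the
#' dominant burst of smoothed displacement energy in the search range
#' `[R + s2_search_start_ms, R + s2_search_rr_frac * RR]`, extended by
#' `s2_pad_ms` on both sides.
#'
#' @param bundle a [recording_bundle()].
#' @param r_peaks integer R-peak indices (see [detect_r_peaks()]).
#' @param config a [pipeline_config()].
#' @return A list of class `beat_segmentation`: `beats` (one row per
#'   beat: windows, `template_r`, flags), `template` (numeric vector),
#'   `processed` (the filtered displacement `hs_signal`).
#' @export
segment_beats <- function(bundle, r_peaks, config = pipeline_config()) {
  if (!inherits(bundle, "recording_bundle")) {
    stop("'bundle' must be a recording_bundle")
  }
  if (length(r_peaks) < 5L) stop("need at least 5 beats to segment")
  fs <- bundle$fs
  proc <- process_sound(bundle, config)
  n <- length(proc$samples)
  r_peaks <- sort(as.integer(r_peaks))
  rr_all <- diff(r_peaks)
  med_rr <- stats::median(rr_all)
  win_len <- as.integer(floor(0.8 * med_rr))

  nb <- length(r_peaks)
  rr_prev <- c(med_rr, rr_all)                 # first beat: neutral
  rr_next <- c(rr_all, med_rr)                 # last beat: neutral
  fits <- r_peaks + win_len - 1L <= n
  # template from beats that fit entirely inside the recording
  wins <- vapply(r_peaks[fits], function(r) {
    proc$samples[r:(r + win_len - 1L)]
  }, numeric(win_len))
  template <- apply(wins, 1L, stats::median)
  template_r <- rep(NA_real_, nb)
  template_r[fits] <- apply(wins, 2L, function(w) {
    suppressWarnings(stats::cor(w, template))
  })

  pvc <- rr_prev < config$pvc_rr_frac * med_rr
  post_pvc <- rep(FALSE, nb)
  for (i in which(pvc)) {
    post_pvc[intersect(i + 1:2, seq_len(nb))] <- TRUE
  }
  post_pvc <- post_pvc & !pvc
  noisy <- is.na(template_r) | template_r < config$noisy_r

  ms <- function(v) as.integer(round(v * fs / 1000))
  s1_start <- r_peaks
  s1_end <- pmin(n, r_peaks + ms(config$s1_ms))
  s2_start <- s2_end <- rep(NA_integer_, nb)
  energy <- proc$samples^2
  smooth_n <- ms(25)
  kern <- rep(1 / smooth_n, smooth_n)
  env <- as.numeric(stats::filter(energy, kern, sides = 2))
  env[is.na(env)] <- 0
  for (i in seq_len(nb)) {
    a <- r_peaks[i] + ms(config$s2_search_start_ms)
    b <- min(n, r_peaks[i] + as.integer(round(config$s2_search_rr_frac *
                                              rr_next[i])))
    if (a >= b) next
    seg <- env[a:b]
    p <- which.max(seg)
    burst <- seg > 0.2 * seg[p]
    lo <- p; while (lo > 1L && burst[lo - 1L]) lo <- lo - 1L
    hi <- p; while (hi < length(seg) && burst[hi + 1L]) hi <- hi + 1L
    s2_start[i] <- max(r_peaks[i] + ms(150), a + lo - 1L - ms(config$s2_pad_ms))
    s2_end[i] <- min(n, a + hi - 1L + ms(config$s2_pad_ms))
  }

  beats <- data.frame(beat = seq_len(nb), r_index = r_peaks,
                      rr_prev = rr_prev, rr_next = rr_next,
                      s1_start = s1_start, s1_end = s1_end,
                      s2_start = s2_start, s2_end = s2_end,
                      template_r = template_r,
                      pvc = pvc, post_pvc = post_pvc, noisy = noisy,
                      accepted = !(pvc | post_pvc | noisy) & fits &
                        !is.na(s2_start))
  structure(list(beats = beats, template = template, processed = proc),
            class = "beat_segmentation")
}

#' @export
print.beat_segmentation <- function(x, ...) {
  cat(sprintf("<beat_segmentation> %d beats: %d accepted, %d pvc, %d post-pvc, %d noisy\n",
              nrow(x$beats), sum(x$beats$accepted), sum(x$beats$pvc),
              sum(x$beats$post_pvc), sum(x$beats$noisy)))
  invisible(x)
}

#' Run the full per-beat analysis on a recording
#'
#' Detects beats from the ECG, segments and quality-filters them, then
#' for every accepted beat estimates the S2 splitting interval from the
#' processed heart-sound snippet and, when pressures are present, the
#' interventricular relaxation dyssynchrony from the paired LV/RV beat
#' windows. Per-recording medians and quartiles summarise the accepted
#' beats.
#'
#' @param bundle a [recording_bundle()].
#' @param config a [pipeline_config()].
#' @param r_peaks optional pre-computed R-peak indices; detected from
#'   the ECG when omitted.
#' @return A list of class `pipeline_result`:
#'   \describe{
#'     \item{beat_table}{one row per beat with acceptance flags,
#'       `split_ms` + `split_status`, and `ird_ms` + `peak_r` when
#'       pressures exist.}
#'     \item{summary}{counts plus `median (25th, 75th percentile)` of
#'       splitting interval and IRD over accepted, successfully
#'       estimated beats.}
#'     \item{segmentation}{the [segment_beats()] result.}
#'   }
#' @export
run_pipeline <- function(bundle, config = pipeline_config(),
                         r_peaks = NULL) {
  if (!inherits(bundle, "recording_bundle")) {
    stop("'bundle' must be a recording_bundle")
  }
  if (is.null(r_peaks)) {
    r_peaks <- detect_r_peaks(bundle$ecg,
                              threshold = config$r_threshold,
                              refractory_ms = config$r_refractory_ms,
                              band = config$r_band)
  }
  seg <- segment_beats(bundle, r_peaks, config)
  beats <- seg$beats
  fs <- bundle$fs
  have_pressure <- !is.null(bundle$lvp) && !is.null(bundle$rvp)

  beats$split_ms <- NA_real_
  beats$split_status <- NA_character_
  beats$ird_ms <- NA_real_
  beats$peak_r <- NA_real_
  for (i in which(beats$accepted)) {
    snip <- hs_signal(seg$processed$samples[beats$s2_start[i]:beats$s2_end[i]],
                      fs)
    res <- estimate_splitting(snip, config$start)
    beats$split_status[i] <- res$status
    if (res$status == "ok") beats$split_ms[i] <- res$interval_ms
    if (have_pressure) {
      w0 <- beats$r_index[i]
      w1 <- min(length(bundle$lvp$samples),
                w0 + min(as.integer(round(config$pressure_window_ms * fs / 1000)),
                         beats$rr_next[i]))
      ird <- tryCatch(
        compute_ird(hs_signal(bundle$lvp$samples[w0:w1], fs),
                    hs_signal(bundle$rvp$samples[w0:w1], fs),
                    max_lag_ms = config$ird_max_lag_ms),
        error = function(e) NULL)
      if (!is.null(ird)) {
        beats$ird_ms[i] <- ird$ird_ms
        beats$peak_r[i] <- ird$peak_r
      }
    }
  }
  if (!any(beats$accepted)) stop("no beats were accepted")

  q <- function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(c(median = NA_real_, q25 = NA_real_,
                             q75 = NA_real_))
    c(median = stats::median(v),
      q25 = unname(stats::quantile(v, 0.25)),
      q75 = unname(stats::quantile(v, 0.75)))
  }
  summary <- list(n_beats = nrow(beats),
                  n_accepted = sum(beats$accepted),
                  n_discarded = sum(!beats$accepted),
                  n_split_ok = sum(beats$split_status == "ok", na.rm = TRUE),
                  split = q(beats$split_ms),
                  ird = q(beats$ird_ms))
  structure(list(beat_table = beats, summary = summary, segmentation = seg,
                 config = config),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<pipeline_result> %d beats, %d accepted (%d splits ok)\n",
              s$n_beats, s$n_accepted, s$n_split_ok))
  cat(sprintf("  S2 split: %.1f (%.1f, %.1f) ms\n",
              s$split["median"], s$split["q25"], s$split["q75"]))
  if (!is.na(s$ird["median"])) {
    cat(sprintf("  IRD:      %+.1f (%+.1f, %+.1f) ms\n",
                s$ird["median"], s$ird["q25"], s$ird["q75"]))
  }
  invisible(x)
}
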