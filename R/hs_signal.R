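#' Uniformly sampled signal container
#'
#' `hs_signal` is the carrier for every signal the package handles: heart
#' sounds and seismocardiographic accelerations, ECG leads, and ventricular
#' pressures. It stores the raw samples together with the sampling rate so
#' that downstream operations (filtering, time-frequency analysis, lag
#' estimation) can always convert between sample indices and physical time.
#'
#' @param samples numeric vector of sample values; must be non-empty and
#'   finite.
#' @param fs sampling rate in Hz (single positive number).
#' @param start_time time of the first sample in seconds (default 0).
#' @param units free-text label for the physical units of `samples`
#'   (e.g. `"m/s^2"`, `"mmHg"`, `"mV"`); informational only.
#'
#' @return An object of class `hs_signal`: a list with elements `samples`,
#'   `fs`, `start_time` and `units`.
#'
#' @examples
#' s <- hs_signal(sin(2 * pi * 5 * (0:999) / 1000), fs = 1000)
#' signal_duration(s)
#' @export
hs_signal <- function(samples, fs, start_time = 0, units = "") {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) {
    stop("an hs_signal needs at least one sample")
  }
  if (!all(is.finite(samples))) {
    stop("all samples must be finite")
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("fs must be a single positive number (Hz)")
  }
  if (!is.numeric(start_time) || length(start_time) != 1L ||
      !is.finite(start_time)) {
    stop("start_time must be a single finite number (seconds)")
  }
  structure(
    list(samples = samples, fs = fs, start_time = as.numeric(start_time),
         units = as.character(units)[1L]),
    class = "hs_signal"
  )
}

is_hs_signal <- function(x) inherits(x, "hs_signal")

assert_hs_signal <- function(x, arg = deparse(substitute(x))) {
  if (!is_hs_signal(x)) stop(sprintf("'%s' must be an hs_signal object", arg))
  invisible(x)
}

#' Number of samples in a signal
#' @param x an `hs_signal`.
#' @return Integer sample count.
#' @export
n_samples <- function(x) {
  assert_hs_signal(x)
  length(x$samples)
}

#' Duration of a signal in seconds
#'
#' Defined as `(n - 1) / fs` for `n` samples, i.e. the time spanned between
#' the first and the last sample.
#'
#' @param x an `hs_signal`.
#' @return Duration in seconds.
#' @export
signal_duration <- function(x) {
  assert_hs_signal(x)
  (length(x$samples) - 1L) / x$fs
}

#' Time axis of a signal
#' @param x an `hs_signal`.
#' @return Numeric vector of sample times in seconds.
#' @export
signal_times <- function(x) {
  assert_hs_signal(x)
  x$start_time + (seq_along(x$samples) - 1L) / x$fs
}

#' @export
print.hs_signal <- function(x, ...) {
  cat(sprintf("<hs_signal> %d samples @ %g Hz (%.4g s)%s\n",
              length(x$samples), x$fs,
              (length(x$samples) - 1L) / x$fs,
              if (nzchar(x$units)) paste0(" [", x$units, "]") else ""))
  invisible(x)
}

#' @export
length.hs_signal <- function(x) length(x$samples)

#' Zero-phase Butterworth bandpass filter
#'
#' Applies a Butterworth bandpass of the given design order forward and
#' backward (via [signal::filtfilt]) so that the output has zero phase
#' distortion: band-limited features keep their timing, which matters for
#' every lag estimate in this package. Edges are handled by odd-symmetric
#' reflection padding before filtering, so short snippets do not pick up
#' start-up transients.
#'
#' @param ts an `hs_signal`.
#' @param low lower passband edge in Hz; `0 < low < high`.
#' @param high upper passband edge in Hz; must be below the Nyquist
#'   frequency `fs / 2`.
#' @param order Butterworth design order of the single-pass filter
#'   (default 2); the forward-backward application doubles the effective
#'   attenuation.
#'
#' @return An `hs_signal` of the same length, sampling rate and units.
#' @examples
#' t <- (0:999) / 1000
#' x <- hs_signal(sin(2 * pi * 150 * t) + sin(2 * pi * 10 * t), fs = 1000)
#' y <- bandpass(x, 50, 250)   # keeps the 150 Hz tone, removes 10 Hz
#' @export
bandpass <- function(ts, low, high, order = 2L) {
  assert_hs_signal(ts)
  fs <- ts$fs
  if (!(low > 0 && high > low)) stop("need 0 < low < high")
  if (high >= fs / 2) {
    stop(sprintf("upper edge (%g Hz) must be below the Nyquist frequency (%g Hz)",
                 high, fs / 2))
  }
  filt <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  apply_filtfilt(ts, filt, low)
}

#' Zero-phase Butterworth highpass filter
#'
#' Companion to [bandpass()]: removes content below `low` Hz with a
#' Butterworth highpass applied forward and backward, with the same
#' reflection-padded edge handling. Used to strip sub-band rumble from a
#' heart-sound snippet before time-frequency analysis.
#'
#' @param ts an `hs_signal`.
#' @param low cutoff frequency in Hz; `0 < low < fs/2`.
#' @param order Butterworth design order of the single-pass filter
#'   (default 2).
#' @return An `hs_signal` of the same length, sampling rate and units.
#' @export
highpass <- function(ts, low, order = 2L) {
  assert_hs_signal(ts)
  fs <- ts$fs
  if (!(low > 0 && low < fs / 2)) stop("need 0 < low < fs/2")
  filt <- signal::butter(order, low / (fs / 2), type = "high")
  apply_filtfilt(ts, filt, low)
}

# forward-backward filtering with odd-symmetric reflection padding:
# about 3 time constants of the slowest edge, capped at n - 1
apply_filtfilt <- function(ts, filt, slowest_hz) {
  x <- ts$samples
  n <- length(x)
  np <- min(n - 1L, ceiling(3 * ts$fs / slowest_hz))
  if (np >= 1L) {
    head_pad <- 2 * x[1L] - x[rev(seq.int(2L, np + 1L))]
    tail_pad <- 2 * x[n] - x[rev(seq.int(n - np, n - 1L))]
    xp <- c(head_pad, x, tail_pad)
  } else {
    xp <- x
  }
  yp <- signal::filtfilt(filt, xp)
  hs_signal(yp[(np + 1L):(np + n)], ts$fs,
            start_time = ts$start_time, units = ts$units)
}
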