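#' Stockwell transform amplitude spectrum
#'
#' Computes the S-transform of a signal snippet over an evenly spaced
#' frequency grid and returns the modulus (amplitude) spectrum. For a
#' signal x(t) sampled with step dt, the transform at frequency f and
#' time tau is
#'
#'   S(tau, f) = sum_t x(t) * (f / sqrt(2*pi)) * exp(-(tau - t)^2 f^2 / 2)
#'                      * exp(-i 2 pi f t) * dt
#'
#' i.e. a Gaussian window whose width scales as 1/f (narrow at high
#' frequencies, wide at low frequencies) combined with a Fourier-style
#' fixed phase reference. The signal is treated as zero outside the
#' snippet: no padding or reflection is applied, which is appropriate for
#' envelope-limited heart-sound snippets that begin and end near zero.
#'
#' The implementation evaluates, for each frequency row, the linear
#' convolution of the demodulated signal with the Gaussian window via FFT,
#' which is numerically equivalent to the direct double summation above
#' (the window is truncated where it has decayed below ~1e-19 of its
#' peak).
#'
#' @param ts an `hs_signal` snippet of at least 8 samples.
#' @param fmin,fmax frequency band edges in Hz; `0 < fmin < fmax < fs/2`.
#'   Defaults 50 and 250 Hz, the analysis band used for second heart
#'   sounds.
#' @param fstep frequency grid step in Hz (default 1).
#' @param window_factor widens or narrows the Gaussian window relative to
#'   the standard Stockwell width: `sigma_t = 1 / (window_factor * f)`.
#'   The default 1 is the classical transform (the formula above); values
#'   above 1 trade frequency resolution for time resolution, which the
#'   splitting estimator uses to separate closely timed valve components
#'   (see [start_config()]).
#'
#' @return An object of class `st_spectrum`: list with
#'   \describe{
#'     \item{amplitudes}{numeric matrix, rows = frequencies, columns =
#'       time samples; non-negative.}
#'     \item{freqs}{ascending frequency grid in Hz.}
#'     \item{times_ms}{time axis in ms relative to the snippet start.}
#'     \item{fs}{source sampling rate in Hz.}
#'   }
#' @examples
#' t <- (0:499) / 1000
#' x <- hs_signal(sin(2 * pi * 150 * t), fs = 1000)
#' sp <- stransform(x, 50, 250, 5)
#' sp$freqs[which.max(sp$amplitudes[, 250])]   # ~150 Hz
#' @export
stransform <- function(ts, fmin = 50, fmax = 250, fstep = 1,
                       window_factor = 1) {
  assert_hs_signal(ts)
  x <- ts$samples
  n <- length(x)
  fs <- ts$fs
  if (n < 8L) stop("snippet too short for an S-transform (need >= 8 samples)")
  if (!(fmin > 0 && fmax > fmin)) stop("need 0 < fmin < fmax")
  if (fmax >= fs / 2) {
    stop(sprintf("fmax (%g Hz) must be below the Nyquist frequency (%g Hz)",
                 fmax, fs / 2))
  }
  if (fstep <= 0) stop("fstep must be positive")
  if (!(is.numeric(window_factor) && length(window_factor) == 1L &&
        window_factor > 0)) {
    stop("window_factor must be a single positive number")
  }
  freqs <- seq(fmin, fmax, by = fstep)
  dt <- 1 / fs
  tgrid <- (seq_len(n) - 1L) * dt
  amp <- matrix(0, nrow = length(freqs), ncol = n)
  for (i in seq_along(freqs)) {
    f <- freqs[i]
    fk <- f * window_factor
    # Gaussian window truncated at 9.5 standard deviations
    L <- ceiling(9.5 * fs / fk)
    k <- (-L):L
    g <- (fk / sqrt(2 * pi)) * exp(-(k * dt)^2 * fk^2 / 2)
    y <- x * exp(-2i * pi * f * tgrid)
    m <- stats::nextn(n + 2L * L, c(2L, 3L, 5L))
    yp <- c(y, rep(0 + 0i, m - n))
    # circularly arrange the kernel with its centre at index 1
    gp <- c(g[(L + 1L):(2L * L + 1L)], rep(0, m - 2L * L - 1L), g[1L:L])
    conv <- stats::fft(stats::fft(yp) * stats::fft(gp), inverse = TRUE) / m
    amp[i, ] <- Mod(conv[1L:n]) * dt
  }
  structure(
    list(amplitudes = amp, freqs = freqs,
         times_ms = (seq_len(n) - 1L) * 1000 / fs, fs = fs),
    class = "st_spectrum"
  )
}

#' @export
print.st_spectrum <- function(x, ...) {
  cat(sprintf("<st_spectrum> %d freq rows (%g-%g Hz) x %d time samples @ %g Hz\n",
              length(x$freqs), min(x$freqs), max(x$freqs),
              length(x$times_ms), x$fs))
  invisible(x)
}

# strict local maxima along one amplitude row, with plateau handling:
# a run of equal values counts once, at its leftmost sample, when the
# neighbouring runs are both strictly lower; boundary runs are excluded
row_local_maxima <- function(a) {
  n <- length(a)
  if (n < 3L) return(integer(0))
  r <- rle(a)
  k <- length(r$values)
  if (k < 3L) return(integer(0))
  starts <- cumsum(r$lengths) - r$lengths + 1L
  j <- 2L:(k - 1L)
  hit <- r$values[j] > r$values[j - 1L] & r$values[j] > r$values[j + 1L]
  starts[j][hit]
}

#' Local maxima of an amplitude spectrum
#'
#' With `along = "time"` (the default), finds for every frequency row the
#' time indices that are strict local maxima along the time axis
#' (amplitude greater than both time neighbours). With
#' `along = "frequency"`, finds for every time column the frequency
#' indices that are strict local maxima across frequency -- the raw
#' material the ridge tracker links over time, since each chirp component
#' shows up as one frequency maximum per instant. In both directions,
#' boundary samples are excluded and an exact plateau is reported once,
#' at its leftmost (lowest-index) sample.
#'
#' @param spec an `st_spectrum`.
#' @param along `"time"` or `"frequency"`: the axis along which maxima
#'   are sought.
#' @return A data frame with integer columns `freq_index` and
#'   `time_index` (1-based), one row per local maximum; zero rows if the
#'   spectrum has none.
#' @export
spectrum_local_maxima <- function(spec, along = c("time", "frequency")) {
  if (!inherits(spec, "st_spectrum")) stop("'spec' must be an st_spectrum")
  along <- match.arg(along)
  if (along == "time") {
    out <- lapply(seq_along(spec$freqs), function(i) {
      ti <- row_local_maxima(spec$amplitudes[i, ])
      if (length(ti)) data.frame(freq_index = i, time_index = ti) else NULL
    })
  } else {
    out <- lapply(seq_along(spec$times_ms), function(j) {
      fi <- row_local_maxima(spec$amplitudes[, j])
      if (length(fi)) data.frame(freq_index = fi, time_index = j) else NULL
    })
  }
  out <- do.call(rbind, out)
  if (is.null(out)) out <- data.frame(freq_index = integer(0),
                                      time_index = integer(0))
  rownames(out) <- NULL
  out
}
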