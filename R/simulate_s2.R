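#' @keywords internal
"_PACKAGE"

# default rational instantaneous-frequency laws (a*t + b)/(t + 1), t in ms:
# b is the onset frequency in Hz, a the late-time plateau
.chirp_law_a2 <- c(a = 24.3, b = 451.4)
.chirp_law_p2 <- c(a = 21.8, b = 356.3)

# shared amplitude envelope of both valve components, t in ms over [0, 60]
s2_envelope <- function(t_ms, amp = 1) {
  amp * (1 - exp(-t_ms / 8)) * exp(-t_ms / 16) * sin(pi * t_ms / 60)
}

# run expr with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate one valve component of the second heart sound
#'
#' Generates a single aortic (A2) or pulmonic (P2) component from the
#' nonlinear transient chirp model. Each component lasts 60 ms and is an
#' amplitude-modulated downward chirp:
#'
#' * envelope: `amp * (1 - exp(-t/8)) * exp(-t/16) * sin(pi*t/60)`
#'   with t in ms -- a smooth attack/decay that is exactly zero at both
#'   ends of the 60 ms support;
#' * instantaneous frequency: `f(t) = (a*t + b)/(t + 1)` Hz, a rapid
#'   hyperbolic fall from the onset value `b` (451.4 Hz for A2, 356.3 Hz
#'   for P2) toward the plateau `a` (24.3 / 21.8 Hz);
#' * phase: the running integral of the instantaneous frequency,
#'   `phi(t) = 2*pi * (a*t + (b - a)*log(t + 1)) / 1000`, so that the
#'   local oscillation rate of the waveform equals `f(t)` at every
#'   instant.
#'
#' The A2 law sits above the P2 law at every time point, which is what
#' lets ridge tracking separate the two components on the time-frequency
#' plane.
#'
#' @param which `"A2"` or `"P2"`.
#' @param amp non-negative amplitude scale of the component.
#' @param fs sampling rate in Hz (>= 500; default 1000).
#' @param freq_law optional length-2 numeric `c(a, b)` overriding the
#'   built-in instantaneous-frequency constants for this component.
#'
#' @return An `hs_signal` covering t = 0 .. 60 ms.
#' @examples
#' a2 <- simulate_component("A2")
#' p2 <- simulate_component("P2")
#' @export
simulate_component <- function(which = c("A2", "P2"), amp = 1, fs = 1000,
                               freq_law = NULL) {
  which <- match.arg(which)
  if (!(is.numeric(amp) && length(amp) == 1L && amp >= 0)) {
    stop("amp must be a single non-negative number")
  }
  if (fs < 500) stop("fs must be at least 500 Hz to resolve the chirp onset")
  law <- if (!is.null(freq_law)) {
    stopifnot(is.numeric(freq_law), length(freq_law) == 2L)
    freq_law
  } else if (which == "A2") .chirp_law_a2 else .chirp_law_p2
  a <- law[[1L]]; b <- law[[2L]]
  t_ms <- seq(0, 60, by = 1000 / fs)
  env <- s2_envelope(t_ms, amp)
  phase <- 2 * pi * (a * t_ms + (b - a) * log1p(t_ms)) / 1000
  hs_signal(env * sin(phase), fs, units = "a.u.")
}

# instantaneous frequency in Hz of a component at time t_ms
chirp_frequency <- function(t_ms, which = c("A2", "P2"), freq_law = NULL) {
  which <- match.arg(which)
  law <- if (!is.null(freq_law)) freq_law
         else if (which == "A2") .chirp_law_a2 else .chirp_law_p2
  (law[[1L]] * t_ms + law[[2L]]) / (t_ms + 1)
}

#' Specification of a simulated second heart sound
#'
#' Bundles the parameters of [simulate_s2()]: the true A2-P2 splitting
#' interval, the component amplitudes, the additive-noise SNR and the
#' noise seed. The study protocol this simulator serves varies the split
#' over 10-70 ms, the A2 amplitude over 0.2-5 with the P2 amplitude fixed
#' at 1, and the SNR over 10-30 dB; any positive values are accepted.
#'
#' @param split_ms true A2-P2 interval in ms (>= 0). Values that are not
#'   a multiple of the sample period are rounded to the nearest sample;
#'   the rounded value is recorded as the ground truth.
#' @param amp_a,amp_p non-negative amplitudes of A2 and P2 (defaults 1).
#' @param snr_db signal-to-noise ratio in dB for additive white Gaussian
#'   noise, or `NULL` (default) for a noiseless signal.
#' @param fs sampling rate in Hz (default 1000).
#' @param seed integer seed for the noise generator; required when
#'   `snr_db` is set.
#' @return An object of class `s2_sim_spec`.
#' @export
s2_sim_spec <- function(split_ms, amp_a = 1, amp_p = 1, snr_db = NULL,
                        fs = 1000, seed = NULL) {
  stopifnot(is.numeric(split_ms), length(split_ms) == 1L, split_ms >= 0,
            amp_a >= 0, amp_p >= 0, fs >= 500)
  if (!is.null(snr_db)) {
    stopifnot(is.numeric(snr_db), length(snr_db) == 1L, snr_db > 0)
    if (is.null(seed)) stop("a seed is required when snr_db is set")
  }
  structure(list(split_ms = split_ms, amp_a = amp_a, amp_p = amp_p,
                 snr_db = snr_db, fs = fs, seed = seed),
            class = "s2_sim_spec")
}

#' Simulate a complete second heart sound
#'
#' Builds S2 as the sum of an A2 component starting at t = 0 and a P2
#' component delayed by the splitting interval (aortic closure precedes
#' pulmonic closure in normal splitting), then optionally adds white
#' Gaussian noise scaled to the requested SNR. Noise power is set
#' relative to the mean power of the clean S2 over its full support.
#'
#' @param spec an [s2_sim_spec()], or a numeric splitting interval in ms
#'   (in which case the remaining arguments are forwarded to
#'   `s2_sim_spec()`).
#' @param ... further arguments passed to [s2_sim_spec()] when `spec` is
#'   numeric.
#'
#' @return An `hs_signal` of duration `60 + split_ms` ms with attributes
#'   \describe{
#'     \item{truth_split_ms}{the splitting interval actually realised
#'       (rounded to the sample grid).}
#'     \item{parts}{list with the clean `a2`, delayed `p2` and `noise`
#'       sample vectors, each of full length.}
#'     \item{spec}{the input specification.}
#'   }
#' @examples
#' s2 <- simulate_s2(30)
#' noisy <- simulate_s2(s2_sim_spec(30, snr_db = 20, seed = 1))
#' @export
simulate_s2 <- function(spec, ...) {
  if (is.numeric(spec)) spec <- s2_sim_spec(spec, ...)
  if (!inherits(spec, "s2_sim_spec")) {
    stop("'spec' must be an s2_sim_spec or a numeric split in ms")
  }
  fs <- spec$fs
  a2 <- simulate_component("A2", amp = spec$amp_a, fs = fs)
  p2 <- simulate_component("P2", amp = spec$amp_p, fs = fs)
  n_comp <- length(a2$samples)
  n_delay <- as.integer(round(spec$split_ms * fs / 1000))
  n_total <- n_comp + n_delay
  a2_full <- c(a2$samples, rep(0, n_delay))
  p2_full <- c(rep(0, n_delay), p2$samples)
  clean <- a2_full + p2_full
  noise <- rep(0, n_total)
  if (!is.null(spec$snr_db)) {
    p_sig <- mean(clean^2)
    sd_n <- sqrt(p_sig / 10^(spec$snr_db / 10))
    noise <- with_seed(spec$seed, stats::rnorm(n_total, sd = sd_n))
  }
  out <- hs_signal(clean + noise, fs, units = "a.u.")
  attr(out, "truth_split_ms") <- n_delay * 1000 / fs
  attr(out, "parts") <- list(a2 = a2_full, p2 = p2_full, noise = noise)
  attr(out, "spec") <- spec
  out
}
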