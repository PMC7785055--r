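---
title: "Ridge tracking for second heart sound splitting: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ridge tracking for second heart sound splitting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(s2split)
```

## The measurement problem

The second heart sound is the superposition of two transient components
a few tens of milliseconds apart: A2, from aortic valve closure, and
P2, from pulmonic valve closure. Their separation — the splitting
interval — tracks the relative timing of left- and right-ventricular
relaxation, which makes it attractive as a non-invasive dyssynchrony
index. The components overlap, ring down at similar frequencies, and
vary in relative amplitude, so neither envelope peaks nor simple
spectral features resolve splits at the physiologically interesting
10–40 ms scale. Time–frequency analysis does: on an S-transform
amplitude spectrum, each component leaves a connected crest of local
maxima (a *ridge*), and the time offset between the two strongest
ridges, read at the frequencies they share, estimates the split from a
single beat.

## The S-transform and its window

`stransform()` evaluates, for each frequency `f` on a 1-Hz grid over
50–250 Hz,

    S(tau, f) = sum_t x(t) * (kf/sqrt(2*pi)) * exp(-(tau-t)^2 (kf)^2 / 2)
                       * exp(-i 2 pi f t) * dt

and keeps the modulus. The Gaussian window narrows with frequency
(`sigma_t = 1/(k f)`), so high-frequency rows localize sharply in time
while low rows localize sharply in frequency. The snippet is treated as
zero outside its support — appropriate for envelope-limited S2 snippets
that begin and end near silence — and the implementation computes each
row by FFT-based linear convolution, which `tests/testthat` verifies
against a literal double-summation oracle to below 1e-8 of the spectrum
maximum.

**Window width factor `k` (default 1.5 in `start_config()`, 1 in the
generic transform).** The classical width `k = 1` is 14–20 ms wide over
the 50–70 Hz rows where both valve components concentrate their energy,
and therefore cannot separate components 10 ms apart: in our
simulations the two crests merge into a single ridge and the estimator
abstains below ~12 ms. With `k = 1.5` the window at those rows is 9–13
ms wide and the full 10–70 ms range resolves, at the cost of ~1.5-fold
coarser frequency resolution that the 1-Hz row grid comfortably
absorbs. The transform itself defaults to the classical width; only the
estimator's configuration narrows it.

## Ridge tracking and ranking

For every frequency row the strict local maxima along time are found
(plateaus count once, at their leftmost sample; boundary samples are
excluded). Maxima are linked into ridges from the lowest row upward:
candidate (open ridge, new maximum) pairs are accepted greedily by
smallest time difference, ties toward the earlier maximum, subject to
a tolerance. Each ridge is then graded by the weight factor
`sum(amplitude * frequency)` and the two strongest, provided they share
enough frequency rows, define the splitting interval as the median of
their absolute per-row time differences (even counts: mean of the two
central values).

Parameters, units, defaults and rationale:

* `link_tol_ms = 5` — a component's crest drifts by well under 1 ms per
  1-Hz row except where the two components interfere; 5 ms follows
  genuine crest curvature without hopping between components at splits
  of 10 ms and above. Ties in rank (equal weights) break toward the
  earlier median-time ridge, so output is deterministic.
* `max_gap_hz = 10` — a crest's maximum can vanish for a few rows where
  the components interfere destructively; a ridge may bridge up to
  10 Hz of such rows before it is closed. On a coarser frequency grid
  this bridging is what plain row adjacency would already provide.
* `min_span_hz = 50` — a ridge enters the analysis only if its
  frequency range exceeds 50 Hz. Background blobs have a frequency
  extent set by the window bandwidth (`f/(2*pi)`, i.e. 8–40 Hz across
  the band), so the span rule removes them wholesale.
* `point_sig = 2.5` — a maximum enters the tracker only if it exceeds
  2.5 times the median amplitude of its own row. The row median
  estimates that row's background level (for Rayleigh-distributed noise
  amplitudes the exceedance probability of 2.5x the median is below
  2%), and because it is a *relative* threshold the estimator remains
  exactly invariant to amplitude scaling.
* `ridge_floor = 4` — a surviving ridge must peak above 4 times the
  global median amplitude; chains assembled purely from background
  fluctuations never do. Both floors exist because, without them,
  spurious ridges spanning more than 50 Hz form readily from noise at
  10–20 dB SNR and can outrank the weaker valve component.
* `min_common = 10` — the median time offset is only reported when the
  two top ridges share at least 10 frequency rows; with fewer the
  median would rest on a handful of possibly corrupted rows. Below the
  threshold the result carries status `no_common_frequencies`; with
  fewer than two ridges, `too_few_ridges`.

**Abstention is a feature.** At low signal-to-noise ratios the
estimator increasingly returns a status code rather than a number; the
sweeps report errors over successful rows and the failure count
separately. We consider a refusal strictly preferable to a silent
20–50 ms blunder, and the per-beat status codes propagate through the
recording pipeline so that downstream medians are taken over credible
estimates only.

**The 50 Hz highpass.** The snippet is highpass filtered (second-order
Butterworth, forward–backward) rather than bandpass filtered to the
analysis band: the later valve component holds appreciable energy just
below 50 Hz whose leakage into the lowest analysis rows strengthens
exactly the rows that anchor its ridge. All filtering in the package is
zero-phase, because any group delay would bias the time comparisons the
package exists to make; "order" always names the single-pass design
order.

## The S2 simulator

`simulate_s2()` builds each component as an amplitude-modulated
downward chirp on a 60 ms support:

* envelope `amp * (1 - exp(-t/8)) * exp(-t/16) * sin(pi*t/60)`, t in
  ms — zero at both ends, peaking near 17 ms;
* instantaneous frequency `f(t) = (a*t + b)/(t + 1)` Hz with
  `(a, b) = (24.3, 451.4)` for A2 and `(21.8, 356.3)` for P2 — a
  hyperbolic fall from several hundred Hz at onset through the analysis
  band into a low-frequency ring-down, with A2 above P2 at every age;
* phase as the running integral of `f(t)`, the standard chirp
  construction, so the waveform's local oscillation rate equals `f(t)`
  at every instant.

The phase construction is the one genuinely open modelling choice, and
we settled it by physical argument: among the readings of the
instantaneous-frequency law we examined, only the integral construction
leaves a substantial fraction of component energy inside the 50–250 Hz
analysis band. A construction in which the waveform's oscillation rate
collapses below 30 Hz within a few milliseconds leaves ~3% of the
energy above the 50 Hz highpass, which is incompatible with estimating
splits from noisy signals at 10–30 dB SNR at all. The law's constants
are exposed (`freq_law`) for anyone wishing to explore alternatives.

S2 is A2 plus P2 delayed by the splitting interval (aortic closure
first, as in normal splitting); non-integer sample delays are rounded
and the realised value recorded as the ground truth. Optional white
Gaussian noise is scaled to a target SNR against the mean power of the
clean signal over its full support and generated from an explicit seed;
the caller's RNG state is left untouched. White noise is a deliberate
simplification — recordings contain structured interference (muscle
noise, rubbing, mains hum) that white noise does not emulate, so the
noise sweep characterises robustness to broadband noise only.

## Pressure-lag estimation

`compute_ird()` mirrors standard practice for timing comparisons
between pressure waveforms: both traces are bandpass filtered
(0.5–40 Hz, order 2, zero phase), normalized to [0, 1], and the LV
downslope — from the pressure peak (earlier sample on ties) to the
first crossing below 0.1, a window that isolates the relaxation fall
while excluding the diastolic baseline — is correlated against
equally long RV segments at every integer-sample lag within ±100 ms.
The reported lag is signed so that a positive value means the LV
downslope leads. No sub-sample interpolation is attempted; the lag grid
is the sample grid. Degenerate inputs fail loudly: constant signals
cannot be normalized, downslopes shorter than 10 samples are rejected,
and lags without full segment overlap are dropped from the correlation
curve (an error only if none remain).

## The synthetic recording generator

`make_fixture_recording()` emulates the structure of an instrumented
open-chest recording: an ECG with impulse-like R complexes on a regular
RR grid, a heart-sound channel with an S1 noise burst 30 ms after each
R and a simulated S2 320 ms after it, and smooth LV/RV pressure beats
(raised-cosine upstroke, exponential relaxation) whose RV timing is
shifted by the programmed IRD. One S1 waveform is drawn per recording
and reused across beats, because beat-to-beat repeatability of S1
morphology is precisely what makes a median-beat template a usable
reference — per-beat random S1 shapes would misrepresent real data in
the direction of making template screening uselessly strict. Premature
beats are emulated by advancing the R complex by 35% of an RR interval,
which triggers the pipeline's RR-based ectopy rule. Channel noise is
white and seeded.

What the generator does not emulate: respiratory modulation of the
split or of amplitudes, baseline wander, electrode artifacts,
inter-beat split variability beyond what the caller programs, sensor
transfer functions, or pacing artifacts. Passing the end-to-end
recovery tests therefore demonstrates the pipeline's internal
consistency — segmentation, screening, window placement and estimator
composition — not robustness to everything field data can contain.

## The recording pipeline

`run_pipeline()` chains: R-peak detection (10–40 Hz bandpass, squared,
adaptive threshold at 0.4 of a rolling 2-s maximum, 200 ms refractory
period, strongest-candidate-first selection); accelerometer combination
(per-sample Euclidean norm of mean-removed axes, skipped when a
combined channel is supplied); double integration to displacement with
a 2 Hz zero-phase highpass after each pass to kill integration drift;
50–250 Hz bandpass; beat alignment on R with a median-beat template
over 0.8 of the median RR; flags (`pvc` when the preceding RR is below
0.8 of the median RR, `post_pvc` for the following two beats, `noisy`
when template correlation falls below 0.8); S1 window `[R, R+120 ms]`;
S2 window as the dominant smoothed-energy burst in
`[R+200 ms, R+0.6 RR]` padded by 40 ms; then the splitting estimator on
each accepted S2 snippet and the pressure-lag estimator on each beat's
pressure windows. Summaries are medians with 25th/75th percentiles over
accepted beats. The R-peak, window and screening constants are
operational stand-ins for what is done by eye in practice; each is a
`pipeline_config()` field.

The bundle container assumes its channels are already time-aligned;
aligning against a synchronisation pulse is acquisition-system work
that happens before this package sees the data.

## Problem sizes and determinism

The shipped tests and the acceptance script run the full validation
grids: 61 noiseless splits (10–70 ms), 25 amplitude ratios (0.2–5.0),
21 SNR levels (10–30 dB, one seeded realisation each), 50-seed
pressure-lag recovery, and 10–20-beat synthetic recordings. Every
random quantity flows from an explicit seed through a
state-restoring wrapper, so all results — including whole pipeline
runs — are bitwise reproducible.

## Known limitations

* The estimator reports the interval unsigned and does not label which
  ridge is A2: reversed splitting is indistinguishable from normal
  splitting by this algorithm. The signed per-frequency offsets and the
  earlier-ridge identity are exposed for downstream use.
* Below ~19 dB SNR the abstention rate grows (roughly half of
  realisations near 12 dB), and the occasional accepted estimate can be
  off by up to a few milliseconds; noisy snippets are better handled by
  aggregating per-beat medians across a recording than by trusting any
  single beat.
* At a 1 kHz sampling rate the estimate is quantised to 1 ms, and a
  systematic bias of about one sample (the later component's crest
  leads its own onset slightly more than the first component's) puts
  most noiseless estimates 1 ms below the programmed value.
* The pressure-lag estimator assumes one dominant peak per analysed
  window; multi-peak windows (severe ectopy, catheter artifacts) will
  anchor the downslope on the wrong peak.
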