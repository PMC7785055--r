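# s2split

Splitting of the second heart sound (S2) — the delay between its aortic
(A2) and pulmonic (P2) valve components — carries direct information
about the relative timing of left- and right-ventricular relaxation.
Widened splitting accompanies delayed right-ventricular emptying;
narrowed splitting accompanies delayed left-ventricular emptying, as in
left bundle branch block and during biventricular pacing. Measuring the
A2–P2 interval from a *single* heartbeat is hard because the two
components overlap within a few tens of milliseconds and change shape
from beat to beat and subject to subject.

`s2split` implements a single-heartbeat estimator of the A2–P2 splitting
interval based on amplitude ridge tracking on the Stockwell
(S-) transform, together with everything needed to exercise and validate
it without any recordings: a chirp-model simulator of S2, an estimator
of interventricular relaxation dyssynchrony (IRD) from paired
ventricular pressures, a beat-segmentation pipeline for multi-channel
recordings, and the simulation sweeps that quantify accuracy.

## The estimator

For a segmented S2 snippet x(t) (50 Hz zero-phase highpassed), the
S-transform amplitude spectrum is

    A(τ, f) = | Σ_t x(t) · (kf/√(2π)) · exp(−(τ−t)²(kf)²/2) · e^(−i2πft) · Δt |

over f = 50…250 Hz — a Gaussian window whose width scales as 1/f
(width factor k, default 1.5). The algorithm then

1. finds, in every frequency row, the significant local maxima of
   A(τ, f) along time;
2. links maxima in adjacent rows into **ridges** (time difference ≤ 5 ms),
   keeping ridges whose frequency range exceeds 50 Hz;
3. grades each ridge by the **weight factor** Σ amplitude × frequency —
   a proxy for the energy it carries — and normalizes to the strongest;
4. takes the two strongest ridges as the signatures of A2 and P2 and
   reports the **median time offset between their common frequencies**
   as the splitting interval.

When no credible ridge pair exists (no second component, or heavy
noise), the estimator returns a status code instead of a number.

IRD is estimated independently as the lag that maximizes the Pearson
correlation between the normalized LV pressure downslope and the
shifted RV pressure (positive IRD = LV relaxes earlier), after 0.5–40 Hz
zero-phase Butterworth filtering.

## Worked example

```r
library(s2split)

## simulate one S2 with a 40 ms split and estimate it back
s2 <- simulate_s2(40)
estimate_splitting(s2)
#> <split_result> interval 39.00 ms (2 ridges, 159 common rows)

## a full synthetic recording: 20 beats, programmed split 40 ms,
## IRD +8 ms, 20 dB channel noise
fx <- make_fixture_recording(n_beats = 20, split_ms = 40, ird_ms = 8,
                             snr_db = 20, seed = 1)
run_pipeline(fx)
#> <pipeline_result> 20 beats, 20 accepted (20 splits ok)
#>   S2 split: 39.0 (38.8, 40.0) ms
#>   IRD:      +8.0 (+8.0, +9.0) ms

## accuracy across the full splitting range, noiseless
sweep_intervals()
#> <sweep_result> interval: 61 rows (0 without estimate)
#>   mean_error: -0.9016
#>   mean_abs_error: 0.9016
#>   rmse: 0.9495
#>   max_abs_error: 1
#>   pearson_r: 0.9999
#>   r_squared: 0.9998
```

The estimate of a single simulated beat is 39 ms against a programmed
40 ms — the estimator carries a small negative bias (≤ 1 ms, one sample
at 1 kHz) because the later component's ridge crosses each frequency
slightly earlier relative to its own onset than the first component's
does. The pipeline recovers both the programmed splitting interval and
the programmed pressure-downslope delay as per-recording medians with
quartiles.

A command-line front end for simulation, single-file scoring, IRD,
sweeps and the pipeline is installed at
`system.file("cli", "s2split.R", package = "s2split")`.

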