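---
title: "Methods: spatiotemporal analysis of spontaneous pacemaker activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatiotemporal analysis of spontaneous pacemaker activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pacemap)
```

# The measurement problem

Monolayer cultures of neonatal ventricular cardiomyocytes beat
spontaneously: the coupled network synchronizes by mutual entrainment and
every excitation originates from the momentarily fastest pacemaker region,
usually at the periphery of the 8-mm culture disc. Recorded on a
12-electrode stretchable microelectrode array (10 kHz per channel), each
beat appears as a cluster of biphasic unipolar electrograms, one per
electrode, whose steep downstroke (typically < 1 ms) marks the local
activation time. Two kinds of variability carry the physiology:

* **temporal** — the interbeat-interval (IBI) series fluctuates with
  power-law (fractal) statistics, as heart rate does in vivo;
* **spatial** — the site of origin jumps between competing pacemaker foci,
  visible as abrupt changes of the propagation direction.

`pacemap` implements the full chain from raw multichannel samples to the
summary markers of both kinds, plus the epoch analysis of the transient
beat-rate response to substrate stretch and release, and a ground-truthed
simulator so that every stage can be validated without real recordings.

# Signal conditioning and activation detection

Each channel passes through a three-sample sliding median (removes
single-sample digitizer glitches exactly), a digital AC-coupling high-pass
`y[k] = a*y[k-1] + a*(x[k] - x[k-1])` with `a = tau/(tau + 1/rate)` and
`tau` = 3 ms (removes baseline drift), and optionally a zero-phase FIR
low-pass with a Kaiser window (cut-off 0.5–3 kHz, default 2 kHz, 60 dB
stopband, 500 Hz transition). The FIR kernel is symmetric and applied with
its group delay compensated, so it cannot shift activation times; the AC
filter is causal, but because the downstroke is much shorter than `tau`
its effect on the derivative minimum is far below one sample.

Activation times are the local minima of the centred-difference first
derivative below a robust threshold, `k` times the derivative's
MAD-based SD with `k = 5`. Two practical choices replace the original
study's manually tuned thresholds and curation GUI:

* a **threshold floor** of 5% of the largest derivative magnitude in the
  trace, which keeps filter artifacts (AC-coupling overshoot after the
  negative phase, FIR pre-ringing — both a few percent of a genuine
  downstroke) out of traces so clean that the robust SD degenerates;
* **no manual curation**: at `k = 5`, Gaussian noise still produces about
  one false local minimum per ~80 channel-seconds. These survive as
  single-electrode "beats" downstream and are flagged ineligible rather
  than deleted, because deleting them is exactly the curation step that is
  out of scope here. A green end-to-end test therefore establishes
  recovery of the true beats plus correct flagging of the residue, not a
  zero false-positive rate.

Fractionated electrograms (several derivative minima within 1 ms) are
fused into a single event at the derivative-magnitude-weighted mean time,
and fusion is idempotent.

# Beats, IBI and integral-preserving beat-rate resampling

Events pooled over electrodes are clustered into beats wherever
consecutive gaps exceed 50 ms — propagation across the 8-mm disc at
~30 cm/s takes ~27 ms, while even stretch-accelerated beating stays above
~250 ms per cycle, so the gap separates beats at all rates seen here. The
beat's mean activation time `m_i` averages the available electrodes; the
IBI series is `diff(m_i)`. Long pauses are retained, never censored.
Beats supported by fewer than 4 electrodes stay in the IBI series but are
excluded from all spatial analysis (a plane fit needs 4 points).

The instantaneous beat rate is the step function `f(t) = 1/IBI` between
consecutive `m_i`. Resampling integrates `f` exactly over 0.5-s bins
anchored at the first beat (the anchor is configurable; the origin is not
identifiable from the data, so the first beat is used for
reproducibility). The construction conserves beat count: the sum of
`rate * dt` over bins equals the number of IBIs exactly, including the
truncated final bin — this is what makes averaging rates across repeats
legitimate.

# Slowness vectors, entropy, PCA

For every eligible beat, ordinary least squares fits
`t_j = t_0 + s_x x_j + s_y y_j` over electrode positions. The coefficient
vector `s` is the conduction **slowness** (s/cm): the spatial gradient of
activation time. Velocity follows as `v = s/||s||^2`, but slowness is the
primary quantity because a symmetric or near-simultaneous activation
pattern drives `||s||` to zero, where velocity diverges — asking for the
velocity of a zero-slowness beat is an error here, not `Inf`.

Spatial complexity is the Shannon entropy (nats) of the 2-D histogram of
slowness-vector tips on a 0.005 s/cm grid. The grid is anchored at the
origin of the slowness plane with half-open bins; the anchor is not stated
in the original analysis and shifts E only marginally, but fixing it makes
the number reproducible. Interbeat slowness differences
`d_i = ||s_{i+1} - s_i||` align with the IBI ending at beat `i+1`; the
positive rank correlation between the two is the signature of pacemaker
takeover (a long cycle is exactly when a competing focus can fire first,
which moves the activation pattern).

PCA runs on activation times offset by the beat mean, over beats with a
complete electrode set only. In a two-dimensional monolayer driven by
planar/radial wavefronts the first two components carry > 90% of the
variance; i.i.d. jitter without wave structure spreads variance across all
components, so this statistic separates structure from noise.

# Detrended fluctuation analysis

The IBI series is cut into non-overlapping, left-anchored segments of
length `n` in {4, 8, 16, 32, 64, 128} (the grid factor is configurable,
e.g. `sqrt(2)`); each segment is cumulatively summed and linearly
detrended. Because a constant offset integrates to an exactly linear
profile, DF(n) is invariant to the series mean, and a constant series is a
degenerate error (DF = 0, log undefined). Per-segment integration is
equivalent to windowing a globally integrated profile, since the window's
starting level is absorbed by the fitted intercept.

Two fluctuation estimators are provided. The default pools all squared
residuals before the square root, which is the computation used by the
physiozoo-style DFA routines; the `"segment-mean"` variant averages
per-segment RMS values. The two differ only where a segment has very few
residual degrees of freedom: at `n = 4` the square root's Jensen gap makes
the segment-mean DF too small, which tilts the log–log slope upward by
about +0.05 for white noise. Only the pooled estimator reproduces the
reference calibration on this grid — white noise alpha near 0.5, Brownian
noise near 1.5, 1/f noise near 1.0 — so it is the default; the other
variant is kept for comparison. The exponent is the least-squares slope of
`log DF(n)` versus `log n`.

# Stretch/release epoch analysis

Motor start/stop pulses on the event channel are thresholded at half
amplitude and labelled stretch/release alternately (protocols always start
with a stretch). For each intervention the IBR series is aligned on motor
start, normalized to the mean rate over the last 5 s before it, and
averaged across repeats. The per-repeat peak is the bin ending at the
first bin edge at or past the motor end — bin [1.5, 2.0) s for the 2-s
uniaxial motor (conventionally plotted at 1.75 s), bin [1.0, 1.5) for the
1.5-s biaxial motor. Missing bins (pauses) are missing, not zero, and a
repeat whose baseline window has no beats is dropped with a warning.

Note a deliberate property of this estimator: the measured peak
fold-change is attenuated relative to the modulation that produced it,
because the rate gain ramps up over the motor phase and the peak bin
integrates across the top of that ramp. In the simulator a programmed
gain of 2 yields an epoch-averaged peak near 1.7–1.8; the in-vivo-style
plots built the same way share this property, so the package reports the
estimator's value rather than back-correcting it.

The substrate-geometry arithmetic is
`area change (%) = 100*((1+e_xx)(1+e_yy) - 1)`: 5% uniaxial strain with
the lateral constriction compensated gives +5% area; 2% equibiaxial gives
+4.04%. Under incompressibility the same percentage is the constriction
along the normal axis, which is why release acts as a z-axis stretch.

# Statistics

Summaries across preparations use median and IQR, with a Shapiro–Wilk
gate (level 0.05) choosing between the one-sample/paired t test and the
Wilcoxon signed rank test, all two-tailed. The signed-rank p-value uses
the normal approximation
`z = (W - n(n+1)/4)/sqrt(n(n+1)(2n+1)/24)` **without** continuity
correction: for 25 positive differences this yields p = 1.23e-5, matching
the values this analysis pipeline is expected to print, whereas the
corrected variant gives 1.30e-5. Ties among absolute differences get
mid-ranks; exact ties with the null are dropped. Rank correlations are
Spearman's rho, displayed against a 5 x 5 quantile-bin density map in
which each cell holds observed count over the count expected under
independence (`n * 0.04`); boundary quantiles fall to the lower cell.

# The synthetic world

`sim_config()` states the world the tests assume; its defaults are fixed
once and are not tuned against outcomes:

* geometry: the 12 recording electrodes on a 2-mm-pitch grid (4 x 4 minus
  corners) inside the 0.4-cm-radius disc; foci on the disc boundary,
  evenly spaced (count and exact angles are free parameters of the
  biology; 4 foci reproduce frequent takeover);
* clocks: per-focus period `base_period * exp(noise)`, `base_period` =
  0.8 s, with per-focus fractal log-period noise of DFA exponent 1.0 and
  SD 0.1 (dimensionless). Independent noise per focus; an optional shared
  component exists and defaults to 0. The winner of each cycle fires and
  resets all clocks — the simplest caricature of mutual entrainment that
  produces takeover, slowness jumps and the positive IBI/slowness-change
  correlation; with `takeover_enabled = FALSE` a single focus runs alone,
  emulating the reduced spatial complexity of contraction-uncoupled
  preparations;
* propagation: radial at 30 cm/s, plus 0.5-ms Gaussian per-electrode
  jitter;
* waveform: three half-cosine segments (3-ms rise, 0.6-ms downstroke,
  5-ms recovery, amplitude 1000), so the derivative is negative only
  inside the downstroke and its single sharp minimum defines the
  activation sample exactly — this is what makes the noiseless
  round-trip-to-one-sample test meaningful;
* nuisance: white noise (SD 20) and a slow sinusoidal drift (amplitude
  100, period 2 s) per channel; optional 12-bit quantization, off by
  default because continuous amplitudes make oracle tests exact;
* stretch: gain ramps to `rate_gain` during the motor movement (2.0 s
  uniaxial / 1.5 s biaxial) and decays with `tau` = 2 s, so the response
  dissipates within ~8 s. Each focus clock advances at rate
  `g(t)/period`, i.e. a cycle ends when the integral of `g` reaches the
  intrinsic period — solved in closed form per protocol segment.

What the simulator does **not** emulate: electrode dropout and chronic
bad channels, amplitude heterogeneity across electrodes, curved or
re-entrant wavefronts, true biophysical pacemaker dynamics (no ion
currents or calcium clocks), or mechanical artifacts during motor
movement. Green tests therefore establish the correctness of the
analysis chain on data with the assumed statistical structure — not
performance on every pathology of real recordings.

# Numerical choices and degenerate inputs

* Median/FIR edges use replication; first/last derivative samples use
  one-sided differences; event times are at sample resolution by default
  (parabolic sub-sample refinement exists but is off, matching the
  sample-resolution convention of the original analysis).
* Beats with collinear available electrodes raise a rank-deficiency
  error rather than returning an ill-conditioned fit.
* `resample_ibr` requires at least two beats; the final partial bin is
  marked and integrates only the covered portion, keeping conservation
  exact.
* Epoch alignment snaps motor start to the IBR bin containing it; with
  0.5-s bins the alignment error is below half a bin and identical across
  repeats of a protocol, and the peak-bin index depends only on the motor
  duration.
* All pipeline stages are deterministic given the recording; rerunning
  `run_pipeline()` writes byte-identical JSON.

# Known limitations

Automated thresholding cannot reproduce a manually curated event set;
residual false positives appear as flagged single-electrode beats (about
one per 80 channel-seconds at default settings) and remain in the IBI
series by design. The slowness fit summarizes each activation by a single
plane, which under-describes curved wavefronts. The entropy depends
mildly on the (fixed) histogram anchor. DFA exponents from the 4–128
grid carry the small-scale bias discussed above; comparisons should use a
single estimator variant throughout.
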