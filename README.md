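# pacemap

Spatiotemporal analysis of spontaneous pacemaker activity in cardiomyocyte
monolayer cultures recorded on 12-electrode stretchable microelectrode
arrays — for cardiac electrophysiologists studying beat-rate variability,
pacemaker-focus dynamics and mechano-electrical feedback in vitro.

Monolayers of ventricular myocytes beat spontaneously; each excitation
starts at the momentarily fastest pacemaker region and sweeps the culture,
producing one biphasic extracellular electrogram per electrode. `pacemap`
turns the raw multichannel samples into the standard markers of this
preparation:

* **Activation detection** — median / AC-coupling / zero-phase Kaiser
  filtering, activation time at the minimum of the first derivative
  (centred differences), derivative-weighted fusion of fractionated
  deflections within 1 ms.
* **Beats and rate** — gap-based clustering into beats, mean activation
  times `m_i = (1/N) Σ_j t_ij`, the interbeat-interval (IBI) series
  `diff(m_i)`, and instantaneous beat rate resampled at 2 Hz by exact
  integration of `f(t) = 1/IBI` (so `Σ r_i Δt` equals the number of IBIs
  exactly).
* **Spatial markers** — per-beat conduction slowness `s = (s_x, s_y)`
  (s/cm) from the least-squares plane `t_j = t_0 + s_x x_j + s_y y_j`,
  velocity `v = s/‖s‖²`, Shannon entropy of the slowness distribution on a
  0.005 s/cm grid, PCA of mean-offset activation times, and interbeat
  slowness differences `‖s_{i+1} − s_i‖`.
* **Temporal fractality** — detrended fluctuation analysis of the IBI
  series (segment lengths 4–128, per-segment integration and linear
  detrending): α = 0.5 white noise, ~1 for 1/f, 1.5 Brownian.
* **Stretch response** — motor-pulse parsing, epoch averaging of the
  normalized beat rate around stretch/release (baseline = last 5 s before
  motor start; peak = bin ending at motor end), areal-strain arithmetic,
  and the accompanying statistics (Shapiro–Wilk-gated t / Wilcoxon
  signed-rank tests, Spearman rank correlation with quantile density
  maps).
* **Synthetic recordings** — a ground-truthed generator (competing
  peripheral pacemaker foci with fractal period noise, winner-resets-all
  entrainment, biphasic waveforms, stretch-protocol modulation) used by
  the test suite to validate the whole chain.

## Worked example

Simulate a 15-min recording with the standard stretch protocol (5% strain
held 1 min, released 2 min, five repeats) and run the full pipeline:

```r
library(pacemap)

cfg <- sim_config(n_foci = 4, duration = 910,
                  stretch_protocol = stretch_protocol(), seed = 1)
gt  <- simulate_beats(cfg)            # ground truth: foci, times, events
rec <- synthesize_electrograms(gt)    # 12 channels @ 10 kHz + event channel
report <- run_pipeline(analysis_config(rec))
report
#> <recording_report>
#>   beats: 1447, mean IBI 0.629 s (rate 1.59 Hz)
#>   slowness entropy E = 1.406 nats (8 bins)
#>   DFA alpha = 0.670
#>   PCA: first two components 96.6% of variance
#>   Spearman rho(IBI, slowness diff) = 0.098
#>   stretch: mean peak fold-change 1.60 over 5 repeats
#>   release: mean peak fold-change 1.20 over 5 repeats
```

Reading the numbers: the culture beats at 1.59 Hz with fractal beat-rate
variability (DFA α = 0.67, between white noise at 0.5 and 1/f at 1);
activation patterns are two-dimensional waves (two principal components
carry 96.6% of the variance) from a handful of peripheral foci (entropy
1.4 nats over 8 occupied slowness bins); focus takeover links long beats
to pattern jumps (ρ > 0); and both stretch and release transiently
accelerate beating (fold-changes 1.60 and 1.20 at the end of the motor
phase), decaying back to baseline within ~8 s.

Individual stages are available directly, e.g.

```r
slowness_to_velocity(c(0.0341, 0))$speed  # 29.33 cm/s
dfa(report$ibi)$alpha
areal_strain(0.02, 0.02)                  # 4.04 (% area change)
```

## Acceptance script

`scripts/acceptance.R` recomputes the package's calibration quantities
from scratch by running the package itself: the mean DFA exponent of 50
white-noise and 50 Brownian-noise series of length 512, the first-two-PC
cumulative variance for 300 simulated peripheral-wave beats, and the
areal strain for the 2% equibiaxial and compensated 5% uniaxial
protocols. Run it from the repository root against the installed package:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Layout

```
R/                  implementation (simulator, detection, beats, spatial,
                    DFA, stretch, stats, pipeline)
tests/testthat/     unit, property and acceptance tests (all synthetic)
scripts/acceptance.R
vignettes/pacemap-methods.Rmd   the methods vignette
inst/extdata/layout12.csv       the 12-electrode example layout
```
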