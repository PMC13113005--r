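---
title: "Methods: windowed plant-mood correlation screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed plant-mood correlation screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the estimand

A surface-electrode recording of a plant's extracellular voltage is a slow,
drifting, positive millivolt signal whose absolute level and polarity depend
on electrode geometry: an AC-coupled differential amplifier measures the
difference between two leaf electrodes against a stem reference, so
repositioning the leads rescales the signal and can invert its sign. Mood
readings from a wrist wearable arrive sparsely (every 10–20 minutes, with
dropouts) on a coarse 0–2 scale. The scientific question is whether any
feature of the plant signal co-varies with the wearer's mood *within* a day,
after everything that is constant within a day — electrode placement,
weather, light regime, sleep — has been removed.

The estimand is therefore a panel-data quantity: the within-day Pearson
correlation between a mood variable and a plant window feature, pooled
across days after day-demeaning. Pooled (level-1) correlations are reported
only as context; they conflate the estimand with between-day confounding and
can reverse its sign (Simpson's paradox), which the package demonstrates
constructively (`simpson_config()`).

## Pairing and features

Each mood reading at time *t* is matched to the raw-voltage window
(*t*−300 s, *t*]. A window with fewer than 10 samples is rejected and
logged; the bound is deliberately permissive — its role is to drop readings
that fall into recording gaps, not to guarantee estimator quality. The
window is reduced to twenty features in four families (statistical,
temporal, spectral, shape). Definitional choices the field leaves open were
fixed as follows, and the test suite pins each one:

* sample SD uses the *n*−1 denominator; skewness and kurtosis use
  *n*-denominator moments (excess kurtosis subtracts 3); IQR uses
  linear-interpolation percentiles (type 7).
* CV divides by the *signed* mean. Signals are positive by construction in
  both the recordings emulated and the generator, so CV > 0 in practice; a
  window mean of exactly zero yields a missing CV, excluded pairwise.
* `jitter` is the sample SD of successive differences and
  `mean_abs_change` the mean absolute successive difference — the standard
  non-redundant pair when the upstream definitions are unstated.
* direction change rate counts sign changes of consecutive non-zero first
  differences per second of window span.
* the periodogram is computed on the mean-removed window after linear
  resampling onto a uniform grid at the nominal rate (robust to timestamp
  jitter; time-domain features use the raw samples). The grid size is
  rounded up to a 5-smooth number so the FFT never degrades to a
  large-prime transform; frequencies remain exact for regularly sampled
  windows. Total power sums all non-zero-frequency ordinates
  (|X<sub>k</sub>|²/m); the five relative band powers partition (0, Nyquist]
  when the band edges span it, and they sum to 1 whenever total power is
  positive. A brute-force DFT oracle pins the implementation to 1e-9
  relative on windows up to 1024 samples.
* peak count/rate use strict local maxima with topographic prominence at
  least half the window SD (computed by a monotone-stack / range-minimum
  algorithm, verified against a naive scan). They are computed as extras
  and excluded from the default 10 × 20 grid, which the canonical
  twenty-feature set fills exactly.

The twenty-feature grid composition (6 statistical + 5 temporal + 7
spectral + 2 moment-shape) is itself a design decision: the four families
as named contain 22 quantities, and the peak metrics are the pair that
never appears in downstream screening tables.

## Mood variables

Negative affect is the *mean* of stress and depression — keeping all
composites on the 0–2 scale; Pearson screens are invariant to this affine
choice. Wellbeing is happiness minus negative affect, the simplest signed
combination; its functional form (unlike its scaling) does affect results
and is flagged as a convention. Rolling variables average the trailing 3
readings (expanding at the start of the series, not resetting at midnight —
day-demeaning later absorbs day offsets; the window length is
configurable). With all readings equal, every mood variable is constant and
each affected cell is excluded as zero-variance rather than propagating
NaN.

## The screen and its inference

All 10 × 20 cells are correlated on pairwise-complete observations with
per-cell *n*. P-values use *t* = *r*√(df/(1−*r*²)) at df = *n*−2 for every
level. At levels 2 and 3 this does *not* deduct the degrees of freedom
absorbed by the day means and trends; back-computation from the published
anchor pairs (r = 0.358, n = 128 → p ≈ 3.3×10⁻⁵ only at df = 126) shows the
convention this reproduces. The corrected alternative
(`df_method = "absorbed"`: df = n−d−1 at level 2, n−2d−1 at level 3) is
implemented and is uniformly more conservative.

BH and Bonferroni flags always use the full grid size *m* = 200, counting
incomputable cells as non-discoveries; the BH step-up is delegated to
`stats::p.adjust(method = "BH", n = m)`, which an independent step-up oracle
cross-checks in the tests. Ties share the larger rank's decision; a p-value
exactly at α/m survives Bonferroni (≤ convention).

Day-inclusion rules: level 2 needs ≥ 2 observations per day (a single
observation cannot be demeaned informatively), level 3 needs ≥ 3 and
non-degenerate observation times. Dropped days are logged on the returned
object.

## The synthetic generator

The generator is first-class, tested code: it produces the statistical
structure the analysis assumes, with known ground truth, so that the
pipeline's recovery behaviour is itself testable. Per day *d* and unit
gain, the plant stream is

> v(t) = b_d + g_d · [ A·circ(t) + α·s(t) + ε(t)·(1 − β·s(t)/2) ]

with deviation reflected as v → C + b_d − (v − b_d) when the day's era has
negative polarity (C = 0 by default keeps signals positive).

* **Baselines b_d** are drawn per day from the configured era ranges
  (defaults A: 25–200 mV, B: 30–1800 mV, matching the scale of the
  motivating recordings' daily means).
* **Gain g_d = b_d / 300 mV.** Electrode placement scales the whole
  differential measurement, not just its offset — the era-level 25–40×
  baseline shifts come with proportionally larger within-day excursions.
  This is what makes the pooled-vs-fixed-effects contrast reproducible: the
  high-gain era dominates the demeaned covariance, so the FE estimate takes
  that era's (measured) sign while the pooled estimate follows the
  day-level confound. The 300 mV reference keeps within-day deviations
  near 10% of baseline, so relative-dispersion features (CV) are driven by
  genuine variability suppression rather than by mean shifts.
* **Circadian drift** is a cosine peaking at 14:00 whose amplitude is
  solved numerically so that, with coupling off, it contributes 14% of
  within-day signal variance over the recording span (the recording covers
  only part of the cycle, so the windowed variance of the sinusoid is
  computed, not assumed to be A²/2).
* **Noise** is stationary AR(1) with marginal SD 8 mV and a 2 s
  correlation time (the AR coefficient is derived from the correlation
  time at the configured sample rate, making the process rate-invariant).
  Seconds-scale memory is the choice consistent with an AC-coupled front
  end whose high-pass corner sits near 0.5 Hz: slower noise components
  would not pass the amplifier.
* **Latent stress** is a Gaussian random walk at 1-minute resolution
  (step SD 0.04), reflected into [0, 2], plus a per-day offset
  (SD 0.3) that induces between-day confounding; it is linearly
  interpolated to sample resolution. Readings add N(0, 0.2) noise and are
  clipped; happiness and depression are clipped linear transforms of latent
  stress with slopes −0.5 and +0.5.
* **Couplings**: α = 14 mV per unit stress and β = 0.15 (fractional noise-SD
  suppression per unit stress) were calibrated so the day-demeaned screen
  at n ≈ 128 lands at FE r(stress_rolling, mean) ≈ +0.32 and
  FE r(stress_rolling, CV) ≈ −0.32 — the effect-size regime of interest.
  The suite asserts sign recovery for both cells in at least 95 of 100
  seeded replicates; the acceptance script reports the measured rates.
* **Scheduling**: readings at uniform 10–20 minute gaps, each missed with
  probability 0.2; 4 recording hours per day starting 09:00; 10 days with
  the era boundary at day 5. Days are calendar-local; no reading crosses
  midnight.

What the generator does **not** emulate: action or variation potentials,
stimulus-evoked transients, VOC-mediated or electromagnetic coupling
mechanisms, non-stationary electrode drift within an era, heavy-tailed
artifacts, or ground-loop saturation episodes (a configurable rail-clip
filter exists but is off by default). Passing recovery tests therefore
show that the *pipeline* recovers structure of the assumed kind at
realistic sizes — they are not evidence about real plant recordings.

## The confounded-polarity fixture

`simpson_config()` pairs the polarity flip with day-level confounding
(era A: low baselines, high day-stress offsets; era B: high baselines, low
offsets, negative polarity) under a stronger coupling regime (α = −30,
β = 0.6). Two failure modes bound its design: with a small mean coupling
the per-day mean series is circadian-dominated and the era sign flip is
unreliable; with a large one at a small gain reference the window mean
approaches zero on low-baseline days and CV explodes. The fixture holds the
relative mean shift near 10% while making the coupling dominate the
circadian component, and reproduces — in 100 of 100 seeded replicates —
the qualitative pattern: per-day mean correlations negative in era A,
positive in era B (era-dependent), CV negative on at least two-thirds of
evaluable days in both eras (era-invariant), and a pooled-vs-FE sign
reversal for the mean cell.

## Null calibration and a known limitation

With both couplings set to zero the mood series and the plant stream are
independent, yet the screen's p < 0.05 counts exceed the nominal 10 of 200:
roughly 45–55 at level 1, 14–20 at level 2, and 12–15 at level 3 (means
over 100–200 replicate studies). The level-1 inflation is the expected
signature of between-day confounding — it is the very phenomenon the
fixed-effects level exists to remove. The residual level-2/3 inflation has
a different cause: both the rolling mood variables and the smooth plant
features (mean, RMS, trend) are autocorrelated within days, so the
effective degrees of freedom are below n−2 and the naive t-test
over-rejects. A permutation oracle (20,000 shuffles) confirms the analytic
p-values are exact under exchangeable nulls; the inflation is a property of
naive Pearson screening on smooth series, not an implementation defect.
Practical consequence: expected-by-chance counts quoted against 200 tests
should be treated as lower bounds for the smooth feature families, and
level 3 — which removes the dominant shared trend — is the level whose
null behaviour comes closest to nominal. A block-permutation or
effective-df correction would be the natural extension; it is out of scope
here.

## Numerical conventions and degenerate inputs

Zero-variance variables are excluded pairwise with the cell's reason
recorded; per-day evaluability requires n ≥ 3 and per-day variance above
1e-12 (absolute), guarding against float-noise "variance". |r| = 1 reports
p = 0. Reflection and fixed-effects invariance tests assert equality at
1e-12 — floating-point demeaning after adding per-day constants cannot be
bitwise stable, and near-machine tolerance is the honest statement of the
invariance. Duplicate stream timestamps collapse to their mean on read,
with a logged count; unparseable rows are dropped unless they exceed 1% of
the file.

## Problem sizes used by the tests

Replicate-based tests (sign recovery, null calibration, era pattern, the
lag profiles) run the generator at 4 Hz sampling: every window still
clears the matching criterion by two orders of magnitude, and all screened
statistics are window-level quantities whose distributions are set by the
window duration, noise correlation time and coupling sizes rather than by
the raw sample count. The full 120 Hz configuration is exercised once per
acceptance run and in targeted unit tests (spectral calibration, full
pipeline). One hundred seeded replicates back each recovery rate; the
zero-coupling calibration uses two hundred.
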