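---
title: "Respiration-phase coupling of periodic and aperiodic neural activity: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Respiration-phase coupling of periodic and aperiodic neural activity: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

Resting-state M/EEG power spectra decompose into narrowband oscillatory
peaks and a broadband aperiodic background that falls off as
`log10 P(f) = offset - chi * log10 f`. The exponent `chi` (the "1/f
slope") indexes the balance of excitation and inhibition in the
underlying population: steeper slopes indicate a stronger inhibitory
contribution. Bodily rhythms — respiration in particular — modulate
oscillatory activity; this package implements a pipeline to ask whether
and *when in the breathing cycle* the aperiodic exponent and the
oscillatory (periodic) power are modulated, and whether the two
components follow the same or different temporal dynamics.

## Pipeline overview

1. **Respiratory phase** (`normalize_trace`, `detect_extrema`,
   `interpolate_phase`): the belt signal is z-scored; inspiratory peaks
   and expiratory troughs are local extrema with topographic prominence
   at least 1 (scale-free on the z-scored trace); phase is linearly
   interpolated trough-to-peak (−π → 0) and peak-to-trough (0 → π), so 0
   is peak inspiration and ±π peak expiration. Phase before the first
   and after the last extremum is undefined and those analysis windows
   are dropped — extrapolating phase outside the observed cycle has no
   empirical support.
2. **Time-resolved spectral parameterization** (`stft_spectra`,
   `fit_aperiodic`, `fit_peaks`, `parameterize_recording`): 1-s Hann
   windows, 75% overlap (250-ms hop, 1-Hz resolution, 1–40 Hz), one
   spectrum per window with no cross-window averaging so that the slow
   respiratory modulation is not smeared. Each window gets a robust
   aperiodic fit — an initial log-log line, then a refit restricted to
   points not riding above that line (the 2.5th percentile rule of the
   standard specparam defaults), which excludes oscillatory peaks
   wholesale — and, optionally, iterative Gaussian peak extraction with
   a joint refit of peaks plus aperiodic line.
3. **Phase binning** (`phase_at_windows`, `bin_course`): each window's
   exponent (or band power) is assigned the respiratory phase at its
   centre and collected into 60 overlapping bins (centres π/30 apart,
   half-width π/10, closed boundary; every value lands in exactly 6
   bins), giving a quasi-continuous course of the quantity over the
   cycle.
4. **Inference** (`fit_harmonic_lmem`, `harmonic_modulation_test`): a
   mixed-effects harmonic model
   `value = beta0 + (S1_j + beta_sin) sin(omega) + (S2_j + beta_cos) cos(omega) + e`
   with independent per-subject random slopes; modulation strength is
   the vector norm `v = sqrt(beta_sin^2 + beta_cos^2)` and the preferred
   phase `atan2(beta_sin, beta_cos)`. Significance comes from a
   surrogate null (below); strength is also reported as
   `z = (v - mean(null)) / sd(null)`.
5. **Circular statistics** (`course_circular_mean`, `rayleigh_test`,
   `watson_u2_*`, `circular_median_test`): preferred-phase summaries and
   comparisons of courses within and across channels, parcels and
   conditions.

## Choice of the surrogate null

The null hypothesis is "window values carry no information about
respiratory phase". Three constructions are available in
`harmonic_modulation_test`:

* **`"shift"` (default):** circularly shift each subject's window-value
  sequence by a random lag relative to its phase sequence, then re-bin
  and refit. This preserves the temporal autocorrelation of the values
  (neighbouring 1-s windows share 75% of their data) *and* the
  structure of the phase sequence while destroying their alignment.
* **`"shuffle_windows"`:** permute window values before re-binning.
* **`"shuffle_bins"`:** permute the 60 binned values.

Only the shift null is calibrated here. The overlapping windows and the
6-fold overlapping bins concentrate noise power in the low angular
harmonics of the course; value permutation spreads it evenly, so the
first-harmonic coefficient of the observed course is systematically
larger than under a shuffled null (about a three-fold variance ratio for
bin shuffling at the default windowing), which inflates false positives
badly. The same consideration — that a valid null must preserve
autocorrelation — motivates using IAAFT surrogates of the respiration
trace for the bin-wise percentile bands (`binwise_null_bands`): an IAAFT
surrogate keeps the belt signal's amplitude distribution exactly and its
power spectrum almost exactly, so surrogate phases have realistic
dynamics but no relation to the recording. Shift nulls are the cheap
equivalent for the vector-norm test; the shuffle modes are retained for
comparison.

## The mixed model and its engines

Subject courses are demeaned before fitting (equivalently, a per-subject
fixed intercept): the printed model has no random intercept, yet
baseline slopes differ across subjects, and demeaning makes `v` and `z`
invariant to per-subject constants. Random slopes are modelled
independent — two variance parameters on 60 points per subject is as
much structure as the data support. Estimation is maximum likelihood
(not REML), because permutation inference compares fits across refits.

For balanced data — every subject observed on the same full 60-bin grid
— the ML fixed effects of this random-coefficient model equal the
average of per-subject OLS coefficients exactly, independent of the
variance components. The default engine uses this closed form (and its
per-subject deviations as unshrunken random-slope estimates); it is what
makes thousands of permutation refits affordable. Unbalanced courses
fall back to `lme4::lmer`, and the two engines are cross-checked against
each other in the test suite. Permutation p-values use the
`(1 + #{null >= v}) / (1 + k)` estimator so they are never exactly zero;
`k = 5000` matches common practice for published analyses, while tests
and the acceptance script run `k = 200` for desk-scale runtime.

## Circular summaries of courses

A phase course is not an angle sample, so two conventions are fixed and
documented:

* **Weighted circular mean:** weights `w_k = means_k - min(means)`;
  direction `Arg(sum w_k exp(i omega_k))`. On the full equidistant grid
  the min-subtraction adds a constant that contributes nothing (the
  grid's complex exponentials sum to zero), so the direction equals the
  phase of the course's first harmonic — the same quantity the harmonic
  model estimates.
* **Watson's U² against uniformity:** the min-subtracted weights are
  treated as masses and the Watson functional
  `W * integral (Fhat - F0 - mean)^2 dF0` is evaluated piecewise
  exactly, with the total weight `W` in the sample-size position. This
  reduces to the classical one-sample U² for unit masses, is
  rotation-invariant, grows with modulation depth, and is 0 for a flat
  course.

For parcel-level comparisons of slope vs power dynamics, the two-sample
Watson U² is applied to the per-subject preferred phases of the slope
and power courses (label permutation). A two-sample test needs angle
samples; the per-subject circular means are the natural sample and keep
subject-level variability in the null.

## Accumulated oscillatory power

Band-accumulated periodic power can be read out two ways
(`accumulated_power_course`): evaluating the fitted per-window Gaussian
peak model over the band, or summing the flattened
(aperiodic-removed) spectrum over the band. The band sum is linear in
the spectrum, so its bin average equals the accumulated power of the
bin-averaged periodic spectrum; it is also far more robust at
single-window resolution, where periodogram noise (log10 SD ≈ 0.56 per
bin) makes individual peak fits erratic. `run_parcel_dynamics` therefore
uses the band-sum mode for power courses, on flattened spectra from the
joint peak + aperiodic refit (the refit keeps residuals balanced, which
the band sum relies on). The slope-vs-power comparison uses the first
configured band; the default configuration lists the full 1–40 Hz range
first, but when a parcel's oscillatory activity is confined to a known
band (as for the synthetic alpha source used in the validation runs),
listing that band first concentrates the comparison on frequencies that
actually carry periodic power instead of diluting it across dozens of
signal-free bins.

## The synthetic-data generator

The generator (`synth_config`, `gen_respiration`,
`gen_neural_recording`, `gen_cohort`) encodes the study conditions the
analysis is designed for:

* respiration: ~15 breaths/min with 10% cycle-length and depth
  variability, an asymmetric waveform (inspiration occupies 40% of the
  cycle, mimicking belt morphology and exercising the asymmetric
  phase interpolation), additive sensor noise (SD 0.05 of the ~unit
  cycle amplitude), sampled at 300 Hz;
* neural background: `log10 P = offset - chi(t) log10 f` with
  `chi(t) = chi0 + A cos(phase - phi0)`, `chi0 = 1.5`, default
  modulation depth `A = 0.4` preferring `phi0 = pi` (slope steepest at
  the expiration-to-inspiration transition, the empirically typical
  pattern), built from 1-s stationary segments of spectrally shaped
  Gaussian noise overlap-added every 250 ms under a Hann cross-fade.
  The 1-s segment length gives the synthesis 1-Hz spectral resolution —
  necessary so the spectrum is controlled down to the 1-Hz edge of the
  analysis range — while the 250-ms hop matches the temporal resolution
  of the analysis;
* oscillations: a 10-Hz Gaussian peak (height 0.6 log10 units, SD
  2 Hz) whose linear power follows `1 + 0.5 cos(phase - 0)`;
* cohorts: per-subject modulation depths `A_j ~ N(A, 0.1)` truncated at
  0 (depth is norm-like), per-subject seeds derived from one master
  seed.

What it does *not* emulate: sensor topographies and field spread,
cardiac/ocular artifacts, line noise, spectral knees, non-sinusoidal
modulation shapes, or breath-holds. Passing validation on this
generator shows the estimators and tests recover known phase-locked
structure at realistic SNR; it does not certify behaviour under those
real-data complications.

## Numerical choices and degenerate inputs

* Bin membership uses a closed boundary (distance ≤ π/10); ties sit on
  a measure-zero set, and determinism is preferred over any float-exact
  tie rule.
* Empty bins carry `NA` and are excluded from circular statistics;
  short recordings can under-sample rare phases.
* A maximum flush against the signal border has near-zero topographic
  prominence and is not detected as a breath; with the default
  prominence of 1 this loses at most the first/last partial cycle.
* Constant traces (normalization), constant courses (circular mean),
  all-zero paired differences (signed-rank), and all-identical angles
  (median test) raise typed degenerate-input errors rather than
  returning arbitrary numbers; `watson_u2_uniformity` returns exactly 0
  for a flat course because a flat course *is* uniform.
* Peak extraction: detection threshold 2 SD of the current residual, at
  most 3 peaks, Gaussian SD limited to [1, 12] Hz (all configurable);
  breathing depth integrates the raw, un-normalized trace — z-scoring
  first would erase the amplitude information depth is meant to carry.
* IAAFT stops when the rank permutation stabilizes or after 100
  iterations; the closing rank-remap guarantees the amplitude
  distribution exactly.

## Problem sizes used in validation

The test suite and `scripts/acceptance.R` run the full pipeline on
scaled-down recordings: 60-s (calibration, power and phase recovery;
200, 50 and 30 replicate cohorts of 20 subjects, k = 200 permutations)
and 120-s recordings (parcel dynamics; 12 subjects). These sizes were
chosen once as the smallest at which the 60-bin courses are fully
populated (~24 windows per bin at 60 s) and are stated here so results
can be read in context; the defaults of `synth_config` remain the 5-min
study conditions.

## Known limitations

* The closed-form engine requires balance; heavily gappy courses fall
  back to `lme4` and permutation runs will be slower.
* The bin-wise IAAFT null bands are computed per bin without correction
  for the 60 simultaneous comparisons, mirroring the percentile-band
  convention of the sensor-level literature.
* Pooling cohorts from different recording modalities is plain
  concatenation of subjects; no harmonization covariate is modelled.
* At single-window resolution the fitted-peak power readout is noisy;
  use the band-sum mode (the pipeline default) unless windows are
  averaged upstream.
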