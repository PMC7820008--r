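---
title: "Parametrizing NREM sleep EEG spectra: model, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parametrizing NREM sleep EEG spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nremspec)
library(dplyr)
```

## The model

Scalp EEG during non-rapid-eye-movement (NREM) sleep is dominated by
arrhythmic, scale-free activity whose Fourier spectrum follows a power law,
with rhythmic oscillations — most prominently sleep spindles — superimposed
as localized spectral peaks.  `nremspec` parametrizes an average power
spectrum `P(f)` as

    P(f) = C * f^alpha * P_Peak(f)

or, after taking natural logarithms,

    ln P(f) = ln C + alpha * ln f + ln P_Peak(f)

with three interpretable ingredients:

* **`alpha`**, the spectral exponent: the slope of the log–log spectrum.
  Plausible NREM values lie between −4 and −1; values closer to 0 indicate
  flatter spectra (lighter sleep, older age).
* **`ln C`**, the intercept: a frequency-independent amplitude term that
  mixes neural gain with non-neural factors such as skull thickness.
  `ln C_0` is the crossing at `ln f = 0` (1 Hz); because the 1 Hz crossing
  partially reflects the slope, the package also evaluates the fitted line
  at `ln f = 2, 2.3, 2.5, 2.6, 2.7, 3` (7.4–20 Hz).  Across subjects the
  anchor whose intercept is uncorrelated with `alpha` — empirically near
  `ln f = 2.5` (12.2 Hz) anteriorly and `2.6` (13.5 Hz) posteriorly — is a
  *slope-free* intercept (`slope_free_pivot()`).
* **`ln P_Peak(f)`**, the whitened peak term: zero wherever the spectrum
  sits on its power-law background, positive at oscillatory peaks.  Only
  the maximal peak in the spindle band (9–18 Hz) is quantified: its
  frequency `f_maxPeak` and whitened amplitude `ln P_Peak(f_maxPeak)`.

Together these reduce ~191 binwise power values per channel to four
composite, largely non-redundant numbers.

## From signal to spectrum

`compute_spectra()` implements Welch-style averaged periodograms: 4 s
Hann-tapered windows with 50% overlap (2 s hop), restricted to scoring
epochs in the requested stages (default N2 + N3) and discarding any window
that touches an artifact-marked 4 s segment.  The 4 s window fixes the bin
width at exactly 0.25 Hz for *any* sampling rate; R's mixed-radix FFT
handles non-power-of-two window lengths (996 samples at 249 Hz) without
zero padding.

Two decisions the estimation leaves open are resolved as follows:

* **Normalization.** One-sided density normalization, dividing by
  `sfreq * sum(w^2)` for Hann coefficients `w`, so that the integral of the
  PSD over (0, Nyquist] equals signal variance (Parseval).  Tests assert
  this within 5% on white noise.
* **Windows across epochs.** A window may span adjacent epochs as long as
  every overlapped epoch is in the accepted stage set; any other stage
  breaks eligibility.  The last partial window is dropped.

Mastoid re-referencing and notch filtering are assumed done upstream;
device frequency response is corrected by `build_calibration()` /
`apply_calibration()`: amplitude reduction rates measured at anchor
frequencies for 40 µV and 355 µV test sinusoids are averaged per anchor,
cubic-spline interpolated between anchors (clamped outside), and measured
power is divided by the squared rate.

## Fitting the background

A log–log linear fit on the raw 0.25 Hz grid would over-weight high
frequencies, where log-spaced points crowd.  `to_equidistant_loglog()`
therefore resamples `(ln f, ln P)` by monotone piecewise-cubic Hermite
(PCHIP) interpolation onto an equidistant `ln f` grid whose step is the
smallest consecutive log-spacing of the source grid in the fit range — for
2–48 Hz, `ln 48 − ln 47.75 ≈ 0.00522`, the "0.0052" step.  (The step is a
*log-frequency* spacing even though it is conventionally quoted in Hz.)
PCHIP is used, rather than an ordinary cubic spline, because it cannot
overshoot between knots and so keeps `ln P` monotone where the data are.

`powerlaw_fit()` then runs ordinary least squares of `ln P` on `ln f` over
2–48 Hz, excluding the closed interval 6.0052–17.9948 Hz that carries the
alpha and spindle oscillations (and, implicitly, everything below 2 Hz,
where sweating artifacts and electrode high-pass behavior corrupt the power
law).  No knee parameter is fitted.  `R²` is the squared Pearson
correlation between fitted and observed included points.  Exact
power-law inputs are recovered to better than 1e−9 in both parameters.

One numerical caveat: grid points just *outside* the excluded band are
interpolated from source bins up to one bin *inside* it (the Hermite slope
stencil), so only perturbations that vanish at the boundary-adjacent bins
leave the fit bit-for-bit unchanged.  Spectral peaks with realistic widths
decay far below machine precision at the band edges, so this is
irrelevant in practice; the test suite constructs its shielding checks
accordingly.

## Detecting and quantifying spindle peaks

`detect_peaks()` finds local maxima of `ln P` over 9–18 Hz by first and
second derivative tests:

1. An exact parabola is fitted through every triplet of successive 0.25 Hz
   bins (two-bin overlap, one-bin hop); its slope at the middle bin — the
   central difference `(y[i+1] − y[i−1]) / 2h` — is the first-derivative
   series.  Applying the same operator to that series gives the second
   derivative.
2. The first-derivative series is interpolated by a natural cubic spline;
   sign-change brackets are refined by bisection to 1e−9 Hz.
3. The spline of the second-derivative series is evaluated at each root;
   roots with `P' = 0` and `P'' < 0` are accepted.
4. Each accepted peak is quantified by `whiten_at()`: the spline-interpolated
   `ln P` at the root minus the fitted background `ln C_0 + alpha ln f`,
   and peaks are ranked by that whitened amplitude (ties go to the lower
   frequency).  An empty set propagates as missing data.

Design points worth making explicit:

* Derivative tests run on `ln P` as a function of linear `f`; since any
  strictly increasing transform preserves maxima locations up to the
  method's sampling error, this choice only matters at the numerical
  margin.  It is the plane in which whitened spectra are displayed.
* Roots are only accepted where both derivative splines interpolate, i.e.
  within two bins of the band edges (effective search span ~9.5–17.5 Hz).
* The "shift power positive before subtraction" compatibility option is
  off by default: at accepted maxima of a well-fit spectrum the whitened
  value is positive without it, and the pure subtraction is exactly the
  whitening identity.
* **Localization accuracy.** The central difference carries an `O(h²)`
  truncation bias, `≈ (h²/6) |ln P'''| / |ln P''|` at the root with
  `h = 0.25` Hz.  For well-formed spindle peaks (whitened height ≳ 0.5,
  width 0.3–1 Hz) this is below 0.02 Hz and the whitened amplitude is
  within 2% of truth.  For shallow, broad bumps the local maximum becomes
  nearly degenerate against the tilted background: the bias grows to
  ~0.05–0.1 Hz, and a bump whose maximal gradient never exceeds the
  background slope produces *no* local maximum at all — correctly reported
  as no peak.  This is an inherent resolution limit of derivative tests on
  0.25 Hz bins, not of the root refinement, whose 1e−9 Hz tolerance is far
  finer than the conventional 0.0052 readout grid.

## Topography and spindle classes

`regional_means()` averages `f_maxPeak` over five sagittal regions
(frontopolar Fp1/Fp2, frontal F3/F4/Fz, central C3/C4/Cz, parietal P3/P4,
occipital O1/O2 — the montage has no Pz, so the parietal mean uses the two
lateral channels).  `antero_posterior_profile()` serially subtracts
consecutive regional means (F−Fp, C−F, P−C, O−P); the shifts telescope, so
the total equals the occipital-minus-frontopolar difference.  Most of the
anterior-to-posterior frequency increase concentrates in a single maximal
step, which is taken as the boundary between slow- (rostral) and fast-
(caudal) spindle-dominant channels.  Ties go to the most anterior boundary
with a warning; temporal channels, which belong to no sagittal region, are
classified by their coronal row and flagged `extrapolated`.  A monotone
decreasing profile still classifies (with a warning) so that downstream
tables stay complete.

## Cohort statistics

* `fisher_average()` implements Silver–Dunlap averaging: correlations are
  Fisher-Z transformed, averaged (SD likewise computed on the transformed
  scale) and back-transformed.
* `gated_association()` chooses Pearson/t-test when Shapiro–Wilk (at 0.05)
  accepts normality of each variable or group, Spearman/Mann–Whitney
  otherwise.  Mann–Whitney effect sizes are `eta² = z²/(n−1)` with `z` the
  normal approximation of U; the t-test reports `t²/(t²+df)`.  These
  conversions are conventions, chosen because the source procedures leave
  them unspecified.
* `rueger_test()` implements the Descriptive Data Analysis control:
  channels with `p < 0.05` form spatially contiguous areas under a fixed,
  documented 18-channel scalp adjacency (within-row and adjacent-row
  neighbors; overridable), and an area of size `k` is globally significant
  when at least `ceil(k/3)` of its p-values are ≤ 0.05/3 **and** at least
  `ceil(k/2)` are ≤ 0.05/2.  Fractions use ceilings, boundary p-values
  compare with ≤, singleton areas are allowed, and a disjunctive mode
  exists for sensitivity analysis only.
* `compare_independent_correlations()` uses the Fisher z-test
  `z = (atanh r₁ − atanh r₂) / sqrt(1/(n₁−3) + 1/(n₂−3))`; applied to rank
  correlations it is an approximation, and no equality with any externally
  printed p-value is claimed.
* `run_hypotheses()` chains these into the seven-hypothesis battery (age vs
  slope, peak amplitude and peak frequency; sex vs intercept, peak
  amplitude and peak frequency; IQ vs peak amplitude by sex; age–slope
  correlations compared across IQ groups), each followed by the Rüger-area
  control over channels.

## What the synthetic generators emulate

`synth_spectrum()` realizes the spectral model directly: a power-law
background, Gaussian-in-frequency bumps on the `ln P` axis (heights ≥ 0 in
ln-units, the closed form keeps the oracle maximizer analytic), and
optional i.i.d. Gaussian noise on `ln P` — a good approximation for
spectra averaged over many windows, where log-periodogram noise is near
Gaussian.  `dense_peak_oracle()` brute-force-maximizes the generating
curve on a 1e−4 Hz grid, providing the localization reference.

`synth_timeseries()` builds colored noise by spectral shaping (target
amplitudes `∝ f^(alpha/2)`, uniform random phases, inverse FFT), which hits
the target slope exactly in expectation, then adds Poisson-placed
Hann-enveloped spindle bursts (defaults: 6/min, 13.5 Hz, 25 µV, 1 s) and
wraps everything as an all-N2 recording with a clean artifact mask.

`synth_cohort()` draws per-subject parameters from a Gaussian copula with
planted effects chosen to mirror a realistic adult cohort: 170 subjects,
ages 17–60, ~46% women; age–slope correlation 0.45, age–peak-amplitude
−0.3, age–peak-frequency −0.25; +0.5 ln-units sex effect on the slope-free
intercept and +0.35 Hz on spindle frequency in women; a *null* sex effect
on whitened peak amplitude; IQ–amplitude correlation 0.3 in women, 0 in
men.  The intercept is constructed so the slope-free anchor sits at
`ln f = 2.5` exactly (`lnC_2.5 ⟂ alpha`, `lnC_0 = lnC_2.5 − 2.5 alpha`).
Channel values are the subject value plus independent channel noise; the
noise SDs (e.g. 0.08 for `alpha` against a 0.3 between-subject SD) give
inter-channel correlations near 0.93, typical of scalp EEG parameters, and
this correlation — not any tuning — is what keeps Rüger-area false
positives near the nominal level under the null.  Regional spindle
frequency bases (11.62, 12.05, 13.50, 13.58, 13.61 Hz from frontopolar to
occipital) put ~2 Hz of total antero-posterior shift with the dominant
step between the frontal and central rows.  Three percent of channel peaks
are marked missing, mimicking undetectable spindle peaks.

Two caveats about what passing tests on these generators shows: marginal
distributions are Gaussian-copula idealizations (real parameter
distributions are skewed, which is why the normality gate matters on real
data), and spectra/time series contain no artifacts, arousals or stage
transitions beyond what the mask and hypnogram encode.  Recovery results
on synthetic cohorts therefore validate the estimators and the statistical
plumbing, not robustness to un-modeled recording pathology.

## Problem sizes and determinism

All generator functions take a `seed` and restore the caller's RNG state.
The test suite and the acceptance script use fixed problem sizes chosen to
make sampling error small relative to the tolerances they assert: 100-case
peak sweeps, a 20-minute 250 Hz end-to-end recording (~600 windows),
170-subject cohorts, and 200 null cohorts for the type-I check.

## Known limitations

* No slow/fast spindle two-peak model: only the maximal whitened peak is
  quantified, and the slow/fast label comes from topography, not from
  per-channel dual-peak adjudication.
* No peak-width estimation, no knee parameter, no robust refitting.
* Peak localization degrades for shallow, broad bumps (see above).
* The EDF layer covers continuous 16-bit EDF only — no EDF+ annotations,
  no discontinuous records; staging always comes from the hypnogram file.
* `compare_independent_correlations()` on Spearman coefficients is an
  approximation; eta-squared conversions are conventions.
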