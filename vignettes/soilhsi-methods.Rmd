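---
title: "Methods: hyperspectral soil-type classification and TN calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hyperspectral soil-type classification and TN calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soilhsi)
```

## The analysis

`soilhsi` implements a complete near-infrared hyperspectral-imaging workflow
for soil analysis with two goals:

1. **Soil-type classification** (paddy, red, seashore-saline) from fused
   spectral and image-texture features, and
2. **Total nitrogen (TN) calibration**, comparing *local* per-soil-type
   partial least squares regression (PLSR) models with a pooled *general*
   model.

The processing chain is: white/dark reflectance correction
(`correct_reflectance()`, `I = (I0 - D)/(W - D) * 100`), region-of-interest
mean-spectrum extraction (`mean_roi_spectrum()`), band trimming to the
low-noise 975–1645 nm window (`trim_bands()`), standard normal variate (SNV)
row normalisation followed by column z-scoring fitted on the calibration set
(`preprocess_spectra()`), effective-wavelength (EW) selection by the
successive projections algorithm (`select_effective_wavelengths()`),
gray-level co-occurrence matrix (GLCM) texture statistics at the EWs
(`texture_feature_table()`), RBF support vector machine classification
(`fit_svm()`), and SIMPLS PLSR for TN (`fit_plsr()`), evaluated with RMSEP,
prediction-set `R^2 = 1 - SSres/SStot`, and `RPD = SD(y_pred_set)/RMSEP`.

## Successive projections algorithm

SPA selects a small, minimally collinear subset of bands in three phases:

* **Phase 1 — projection chains.** From every candidate start band, columns
  are greedily appended: at each step every unselected column is projected
  onto the orthogonal complement of the span of the selected ones and the
  column with the largest projected norm wins (ties break to the lowest band
  index for determinism). The implementation deflates the working matrix
  against the newest selected direction; a QR-refactorisation oracle in the
  test suite confirms the two formulations agree exactly.
* **Phase 2 — subset scoring.** Every chain prefix of size
  `m = 1..max_vars` is scored by the leave-one-out RMSECV of an MLR fit with
  intercept, computed exactly from one fit via the PRESS identity
  `e_i/(1 - h_ii)`. The best subset per size forms the RMSECV curve
  (`autoplot()` draws it) and the overall minimiser gives `RMSECV_min`.
* **Phase 3 — variable elimination.** The minimising subset's variables are
  ranked by relevance (predictor SD × |MLR coefficient|), nested
  relevance-ordered subsets are rescored, and the final size is the smallest
  `k` with `RMSECV(k)^2 <= F(1 - alpha; n, n) * RMSECV_min^2` at
  `alpha = 0.25`. The F-test degrees of freedom (`n, n`, the calibration
  count) are isolated in one place; the relevance scan is what lets the
  selector return a parsimonious subset that a pure chain prefix would miss.
  With noiseless responses numerically-zero RMSECVs are treated as reaching
  the minimum so exact supports are recovered.

For classification-oriented selection the response is the soil-type
category code (1/2/3) used as a single continuous variable. This is
scientifically debatable — the coding imposes an ordering on unordered
classes — but it is the convention this pipeline follows; the SVM downstream
does not depend on it.

## GLCM texture

Band images are quantized per ROI by min–max binning onto `L = 64` levels
(`floor(v_norm * L)`, clamped; a constant image maps to level 0). GLCMs are
accumulated symmetrically at distance 1 in the four standard directions
(offsets in image coordinates: 0° = (0,+1), 45° = (−1,+1), 90° = (−1,0),
135° = (−1,−1)), normalised to probabilities, and summarised by energy
`Σp²`, contrast `Σ(i−j)²p`, homogeneity `Σp/(1+(i−j)²)` (inverse difference
moment) and entropy `−Σp ln p` (natural log, `0·ln 0 = 0`); the four
directional values are averaged. Choices the literature leaves open —
per-ROI rather than global scaling, 64 levels as a balance between gray
resolution and count sparsity on a 50 × 50 ROI, the homogeneity denominator
variant, and the log base — are defaults in `glcm_config()` and documented
here so any one of them is a one-line change.

## The synthetic generator

No public dataset accompanies this analysis, so `simulate_soil_dataset()`
generates a cohort with the statistical structure the pipeline assumes. Its
defaults are the study conditions and are not tuned per run:

* **Cohort**: 84 paddy, 57 red, 42 seashore-saline samples (183 total); a
  stratified 2:1 split yields 56/38/28 calibration and 28/19/14 prediction
  samples, 122/61 pooled.
* **Bands**: 200 centers evenly spaced on 975–1645 nm.
* **Spectrum model** (reflectance %, clipped to [0, 100]): class baseline
  (paddy 45, red 48, seashore-saline 35 — saline lowest) + per-sample
  baseline shift `N(0, 4²)` + smooth per-sample tilt/curvature
  (`N(0, 2²)`, `N(0, 1²)` amplitudes) − water trough (Gaussian, center
  1400 nm with class offsets −6/0/+8 nm and per-sample `N(0, 2.5²)` nm
  jitter, sigma 60 nm, depth 12% × class scale 1.0/0.85/1.2 × per-sample
  `N(1, 0.1²)`) − TN absorption (Gaussian at 1000 nm, sigma 30 nm, depth =
  TN × class absorptivity 40/50/65 % per % TN) + i.i.d. band noise
  `N(0, 0.3²)`.
* **TN**: uniform within class ranges 0.088–0.312 (paddy), 0.056–0.262
  (red), 0.038–0.205 (saline) % of dry mass — so the pooled range is
  0.038–0.312 and only range information is assumed.
* **Texture**: one zero-mean, unit-SD spatially correlated field per sample
  (Gaussian-smoothed white noise, circular boundaries), shared across bands
  and scaled by each band's reflectance relative to the spectrum mean —
  surface roughness is wavelength-coherent. Class correlation lengths are
  2 px (paddy), 2.6 px (red) and 7 px (saline), with a log-normal per-sample
  multiplier (SD 0.18): saline is distinctly smoother (higher GLCM
  energy/homogeneity, lower contrast/entropy) while paddy and red are close,
  so texture alone separates saline well but confuses paddy with red.

Three design points deserve comment. First, SNV removes additive offsets
and per-spectrum scale, so class-mean baseline differences carry almost no
class information into the models; the discriminative spectral cues that
survive preprocessing are *shape* cues — here the class-dependent trough
position and the TN feature. The trough-position offsets (and their
per-sample jitter) are therefore the dial that sets spectral class overlap:
the defaults give partially overlapping classes, which is the regime where
fusing texture features helps. Second, between-sample variance must be
spectrally smooth (tilt/curvature terms) rather than independent per band;
otherwise column z-scoring inflates pure-noise bands and the leading
principal components become noise, which real soil spectra do not show.
With the defaults the first four PCs carry roughly 90% of the variance and
a Fisher LDA on them classifies in the mid-80% range. Third, TN enters
through class-specific absorptivities, giving the heterogeneity that makes
local calibration outperform a pooled general model; setting all
absorptivities equal removes that advantage, which the tests use as a
negative control.

What the generator does **not** emulate: scattering physics, moisture or
particle-size confounders correlated with TN, nonlinear detector effects,
spatially structured illumination, or inter-band texture decoherence.
Passing tests therefore demonstrate that the pipeline's inference machinery
behaves correctly under its stated assumptions — not that the published
real-data accuracies would be reproduced on new soil.

## Modeling choices

* **Splits**: per stratum, `floor(2n/3)` samples to calibration after a
  seeded shuffle. Column z-scoring, SPA, SVM grid search and PLSR component
  selection all see calibration rows only; the prediction set never
  influences selection (a leakage test asserts this).
* **SVM**: features are z-scored with calibration statistics so spectral
  and texture blocks are commensurate after fusion; `(c, g)` come from
  5-fold cross-validated accuracy over `log2 c ∈ [−5, 15]`,
  `log2 g ∈ [−15, 5]` in steps of 2, then the model is refit on the full
  calibration set.
* **PLSR**: SIMPLS with a component ceiling of 20; the count is chosen by
  leave-one-out RMSECV. Components are truncated when the deflated
  covariance collapses (rank exhaustion) with a warning.
* **R²** is `1 − SSres/SStot` on the prediction set, consistent with
  RMSEP-based reporting; RPD uses the sample SD (n − 1). A perfect fit
  reports `RPD = Inf` rather than an error.
* **Degenerate inputs** fail loudly: constant spectra in SNV (named by
  sample), zero-variance bands in z-scoring (named by band), `W = D` pixels
  in reflectance correction, rank-deficient MLR subsets, single-class
  calibration sets.

## Problem sizes used in the checks

The acceptance script and tests exercise the full 183-sample, 200-band
cohort for the classification and TN experiments (10 seeds each, medians/
means reported) and smaller cohorts (e.g. 21 samples × 40 bands) for unit
properties, keeping a full run within a few minutes on one CPU. The SPA
oracle comparison enumerates 200 random instances up to 12 × 8 over all
start indices; planted-support recovery uses 25 × 20 noiseless designs over
20 seeds.

## Known limitations

* The ENVI reader supports the common key = value dialect with float
  rasters (types 4/5) and BSQ/BIL/BIP interleaves; exotic header fields are
  ignored.
* SPA scans chains from every start band; cost is quadratic in bands times
  `max_vars` and is comfortable at 200 bands but not intended for
  thousands.
* The category-code regression target for classification-oriented SPA is
  kept for fidelity to the workflow it implements, not endorsed.
* Local TN models need at least 6 samples per class (2:1 split with a
  non-trivial calibration side); realistic use wants far more.
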