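---
title: "Methods: Raman Li/Ce quantification and producer discrimination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Raman Li/Ce quantification and producer discrimination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pelletspec)
```

`pelletspec` estimates the lignin-to-cellulose (Li/Ce) signal ratio of
wood pellets from spot Raman spectra and discriminates pellet
producers chemometrically. This vignette is the package's account of
the underlying procedure: what each stage assumes, which parameters
matter, what the synthetic generator does and does not emulate, and
the numerical conventions that a reimplementation would need to match.

## The measurement model

A spot spectrum is a vector of detector counts on a wavenumber axis
(Raman shift, cm⁻¹) covering 800–1800 cm⁻¹, modeled as

$$ I(\nu) \;=\; w_L\,L(\nu) + w_C\,C(\nu) + b\,B(\nu) + \varepsilon(\nu), $$

where $L$ and $C$ are the lignin and cellulose component spectra
(dominant bands: lignin 1600 cm⁻¹ aryl-ring breathing; cellulose
1095/1123 cm⁻¹ C–C/C–O stretching), $B$ a broad fluorescence
background, and $\varepsilon$ detector noise. The quantity of interest
is $w_L / w_C$, accessed through band statistics of the
background-corrected signal. The analysis assumes the recorded range
contains both band systems entirely and that fluorescence varies
slowly on the scale of a Raman band — the premise behind
rolling-circle correction.

## Preprocessing

Every spectrum passes the identical chain: smooth, remove background,
crop. Smoothing before background estimation keeps single-pixel noise
out of the lower envelope; the stage order is fixed in
`preprocess_spectra()` and recorded in each run's resolved config.

**Savitzky–Golay** (`sg_order = 2`, `sg_frame = 7` points): local
least-squares polynomial smoothing, which preserves polynomial trends
up to the fit order exactly (tested to 1e-9). At the spectrum ends the
same-order polynomial is fitted on the truncated one-sided window —
no reflection padding — so no data are invented next to the crop
edge, where the 1600 cm⁻¹ shoulder sits. The window is deliberately
short: at 1 cm⁻¹ spacing it spans 7 cm⁻¹, well under the narrowest
band FWHM (~19 cm⁻¹), so peak heights are barely attenuated.

**Rolling-circle background** (`rc_radius = 800` cm⁻¹,
`rc_passes = 10`): a circle of fixed radius slides beneath the
spectrum; the envelope it traces follows the broad fluorescence while
dipping under narrow Raman bands. Conventions, since "a circle" is
undefined across unlike units:

* Realized as 1-D grayscale morphological opening (erosion then
  dilation) with a semicircular structuring function, computed in
  compiled code. Circle centers extend past the recorded range so the
  envelope has support near the edges.
* The vertical semi-axis is `radius × (intensity range / axis span)`,
  i.e. the element is a circle in span/range-normalized coordinates
  and an ellipse in physical units — invariant to rescaling of either
  axis. The range is taken from the input spectrum once, which makes
  the baseline translation-equivariant (`baseline(y + c) =
  baseline(y) + c`, tested to float precision).
* Pass $k{+}1$ opens the pointwise minimum of the spectrum and the
  previous baseline. Opening is idempotent and anti-extensive, so the
  iteration is stationary from the second pass; the implementation
  stops early once the iterate no longer changes. Successive passes
  never raise the baseline (tested).
* The implementation agrees with an exhaustive circle-placement
  enumeration (the supremum, over all circle positions fitting under
  the spectrum, of the circle's height at each point) to 1e-6 of the
  intensity range on 500-point grids.

Two documented consequences of the range-normalized element:

* *Monotonicity in radius* (larger radius ⇒ pointwise lower baseline)
  is exact in the continuum but can be violated at the grid level near
  the element's steep edge, where grid-restricted centers cannot
  realize the inner-tangency construction. The violation scale is
  `(range/span)·sqrt(2·r·d)` for grid step `d`; the property test uses
  that allowance.
* The chain is only *nearly* idempotent: re-running it moves points by
  up to ~5% of the intensity range, the sagitta of the normalized
  circle over the band clusters. Likewise, a strong in-window
  fluorescence dome (amplitude comparable to the peaks) is tracked
  incompletely, leaving a smooth residual that inflates both band
  areas and biases Li/Ce by a few percent *common-mode* — identically
  across producers — so ordinal comparisons, correlations and
  classifications are unaffected. Absolute Li/Ce values should not be
  compared across pipelines with different background conventions.

**Crop** retains the closed 800–1800 cm⁻¹ interval.

## Band quantification

Two estimators, both on the corrected signal and both invariant under
global intensity rescaling (tested):

* **Area ratio**: trapezoidal integrals over lignin 1250–1700 cm⁻¹
  and cellulose 980–1150 cm⁻¹, with linearly interpolated virtual
  samples at the exact interval boundaries (making integration
  additive over partitions and insensitive to grid alignment). No
  second, local baseline is subtracted under the band — the global
  correction is the only one, and subtracting another straight line
  would double-count. Negative noise undershoots are integrated
  as-is, which is unbiased under symmetric noise.
* **Height ratio**: maximum corrected intensity within ±10 cm⁻¹ of
  1600 cm⁻¹ over the same at 1096 cm⁻¹. The apex search window
  absorbs the 1095/1096/1098 cm⁻¹ conventions for the cellulose band
  and small calibration shifts; the windowed maximum (rather than the
  value at the exact nominal position) is the default because it is
  the more favorable reading for the height estimator — the scatter
  comparison below is therefore conservative.

Group summaries (`summarize_groups()`) report mean, sd (n−1
denominator) and cv per pellet or per producer, ordered by label;
producer values are means of per-spot values. Error bars in the
report figures are ±1 sd.

## Chemometrics

**Uncentered PCA** (`fit_uncentered_pca()`): SVD of the raw spectra
matrix with neither column centering nor scaling. With spectra that
share a common shape, PC1 captures that shape (including its overall
intensity scale) and PC2 the dominant contrast — here the
lignin/cellulose difference. Variance fractions are squared singular
values over their total; loadings are unit-norm rows with the sign
pinned so each loading's largest-magnitude element is positive (SVD
signs are otherwise arbitrary). Reconstruction, orthonormality, and
agreement with an uncentered Gram-matrix eigendecomposition and with
`prcomp(center = FALSE)` are tested. If the requested analysis range
exceeds the recorded coverage it is intersected with a warning rather
than extrapolated.

**Mahalanobis ellipses**: each group's distance-1 contour — center at
the group mean, semi-axes the square roots of the sample-covariance
eigenvalues, orientation from the leading eigenvector (angle
normalized to (−π/2, π/2]). Every boundary point has Mahalanobis
distance 1 from the mean (tested to 1e-8).

**Fisher LDA** (`fit_lda()`): discriminant directions maximize
between- over within-class scatter, solved as a symmetric generalized
eigenproblem via Cholesky whitening of the within-class scatter; at
most (classes − 1) coordinates. A singular within-class scatter
(possible with 10-dimensional scores and small classes) is regularized
by adding `λI`, `λ = 1e-8·trace(W)/dim`, with a warning. Score inputs
are not standardized before fitting — uncentered PC scores already
carry meaningful relative scales, and standardizing would inflate the
noise components. Classification is by nearest class mean in
discriminant space, with exact ties broken to the lowest class label
for determinism. `MASS::lda` serves as an independent cross-check of
the leading direction in the tests.

## The synthetic generator

`generate_ensemble()` emulates the study layout the pipeline is built
for: 8 producers × 5 pellets × 10 spots = 400 spectra, 50 per
producer, on an 800–1800 cm⁻¹ axis at 1 cm⁻¹ spacing (the spacing is
a free parameter; it is not an instrument constant). Defaults, chosen
once as plausible bench conditions:

* **Composition preset**: producers 1–3 at lignin:cellulose weight
  ratio 1.5, producers 4–8 at 1.0 — a two-regime design encoding only
  the ordinal structure (a high-lignin trio versus the rest), since no
  quantitative per-producer composition is available to emulate.
* **Hierarchy**: lognormal jitter of each component weight at pellet
  level (sdlog 0.05) and spot level (0.08) — wood is heterogeneous,
  and spot-to-spot variation on a pellet surface exceeds
  pellet-to-pellet variation within a producer.
* **Surface/optics nuisances**: lognormal overall intensity scale per
  spot (sdlog 0.20; focus on a rough surface strongly modulates
  collected counts, which is why ratios are used at all), lognormal
  jitter of the instrumental broadening (sdlog 0.10), and
  area-conserving redistribution within the cellulose 1095/1123 and
  lignin 1600/1656 doublets (sd 0.06 and 0.04) emulating
  crystallinity/condensation differences between spots. The last
  mechanism is what makes single-point peak heights scatter while
  band areas stay put — the physical reason the area estimator wins.
* **Background and noise**: fluorescence amplitude uniform on
  0.5–1.5 × the unit peak scale (times the spot's intensity scale),
  i.i.d. Gaussian noise with sd 0.02 (SNR ≈ 50 for a ~10 s benchtop
  acquisition).
* **Instrument profiles**: lab 8 cm⁻¹ FWHM resolution and unit
  noise; handheld 12 cm⁻¹ and 2× noise — a modest, deliberately
  unaggressive degradation.

Peaks are Gaussian, so instrument convolution is exact
(σ² adds) and band areas have closed forms (`true_band_areas()`),
which the tests use as ground-truth oracles. The minor bands filling
the integration ranges are fixed design choices documented in
`make_component()`, not literature constants.

**What passing tests do not show.** The generator omits cosmic-ray
spikes, detector saturation, wavenumber miscalibration,
photobleaching dynamics, Lorentzian/Voigt line shapes and
hemicellulose interference. Results on synthetic ensembles therefore
validate the *pipeline's* correctness and the *relative* merits of
the estimators under controlled heterogeneity — not absolute accuracy
on any particular instrument's spectra.

## Problem sizes and determinism

The test suite runs the full 400-spectrum default ensemble once
(shared across the end-to-end checks) and otherwise uses small
ensembles (tens of spectra) and ≤ 500-point grids for the brute-force
oracles; the whole suite completes in well under a minute. Everything
downstream of a seed is deterministic: identical seed and design give
bit-identical ensembles, and `run_pipeline()` writes its resolved
configuration next to its outputs so every table is regenerable.

## Known limitations

* Absolute Li/Ce values carry a background-convention bias of a few
  percent under strong fluorescence (common-mode; see above).
* The rolling-circle variant implemented here (morphological opening,
  range-normalized element, fixed element across passes) is *a*
  standard construction, stated precisely so it can be matched — other
  software's rolling-circle filters need not agree bit-for-bit.
* Uncentered PCA's variance fractions are dominated by PC1's shared
  shape; they are not comparable to centered-PCA variance fractions.
* No outlier rejection is applied anywhere; unusual spots stay in the
  analysis and are visible as points outside their group ellipse.
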