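---
title: "Detecting ionizing-radiation exposure from ATR-FTIR hyperspectral images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting ionizing-radiation exposure from ATR-FTIR hyperspectral images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Attenuated-total-reflection FTIR imaging with a focal-plane-array (FPA)
detector records, in a single acquisition, 16,384 mid-infrared absorbance
spectra from a ~64 × 64 µm patch of tissue — here the stratum corneum of
mouse ear skin. Ionizing radiation leaves a biochemical signature in this
tissue: DNA conformation changes (O–P–O stretching bands), lipid oxidation
and accumulation (CH stretches, ester carbonyl), and shifts in protein
secondary structure (amide I sub-bands). `radsig` implements the full
analysis chain that turns raw absorbance cubes into a sample-level
exposed/unexposed call:

1. **pixel quality control** — amide signal-to-noise and CO~2~-contamination
   filters, then a noise-ranked cap of 100 pixels per image;
2. **five-step pretreatment** — range clipping, dead-pixel filling, spatial
   median denoising, rubber-band baseline correction, amide-II peak
   normalization;
3. **embedding-based outlier masking** (or a simple centre-region selection);
4. **second-derivative biomarker analysis** — Savitzky–Golay second
   derivatives, group difference spectra, band minima, intensities and
   position shifts;
5. **pixel-level classification with sample-level majority vote**, over five
   model families;
6. **stratified evaluation** — balanced accuracy, ROC/AUC, specificity at a
   fixed sensitivity, permutation significance, by dose and by day.

Because no public dataset of this kind exists, the package ships a seeded
synthetic cohort generator that emulates the statistical structure the
analysis assumes. Every stage is exercised end-to-end on generated data.

# The synthetic data model

## Band model

A control-group pixel spectrum is a sum of 16 Gaussian bands (positions,
relative amplitudes and widths in `synth_band_table()`), a smooth baseline,
a per-pixel atmospheric CO~2~ band at 2300–2400 cm^-1^, and noise:

$$A(\nu) = \sum_i a_i \exp\!\left(-\frac{(\nu - c_i)^2}{2\sigma_i^2}\right)
  + b(\nu) + \mathrm{CO_2}(\nu) + \varepsilon(\nu).$$

Gaussian line shapes are a modelling choice, not a physical claim: they are
the simplest shape with an analytic second derivative, which gives the
derivative stage a closed-form oracle ($g''(c) = -a/\sigma^2$ at the
centre). Widths are set per band class (FWHM ≈ 16–28 cm^-1^) so that the
amide-I sub-bands at 1691/1648/1626 cm^-1^ are resolvable in the second
derivative, as they must be for the biomarker analysis to make sense. The
amide-II amplitude is ~1 so the later peak normalization is close to the
identity and effect sizes keep their nominal scale.

## Radiation effects

Exposure (any dose > 0) perturbs the spectrum in three ways:

* **intensity effects**: each band's second-derivative peak intensity moves
  by its tabulated effect size δ (units of 10^-4^ on the normalized scale),
  up or down. Since a Gaussian's second derivative at centre is
  $-a/\sigma^2$, the generator injects the amplitude change
  $\Delta a_i = \pm\,\delta_i\,\sigma_i^2 \cdot m(\text{day})$;
* **band shifts**: the ester carbonyl moves 1735 → 1743 cm^-1^ and the
  asymmetric O–P–O stretch 1236 → 1240 cm^-1^;
* **a flat dose–response**: all doses from 0.1 to 2 Gy trigger the same
  effect (a threshold-like response); a linear mode is available for
  sensitivity analyses.

The day profile `m(day)` defaults to {5: 0.5, 14: 1.0, 21: 0.9, 49: 0.7,
90: 0.4}: detectability peaks two weeks after exposure — when cells derived
from irradiated basal stem cells have reached the stratum corneum — and
decays with epidermal turnover.

One subtlety is forced by the pipeline itself: spectra are normalized to the
amide-II window maximum, so the reference band's *own* amplitude change is
unidentifiable — injecting it would only rescale every other band and
corrupt their effect sizes. The generator therefore expresses all effects
relative to the reference band (1553 cm^-1^) and injects nothing there; its
table entry is kept for peak extraction and documentation.

## Nuisance structure

* **Baseline**: a gentle quadratic plus a 1/ν scattering term, sized so that
  raw-spectrum amide/CO~2~ ratios clear the QC threshold for most pixels —
  the operating regime the QC stage is designed for, in which a *minority*
  of pixels (high CO~2~ draw, high noise draw, dead) is rejected.
* **Noise**: i.i.d. Gaussian per spectral point (default sd 0.004
  absorbance) plus a heteroscedastic term proportional to the band signal.
* **Dead pixels**: a configurable fraction of pixels multiplied by a factor
  below 0.05, placed uniformly at random.
* **Per-pixel scale**: contact-quality jitter, multiplicative, sd 3%.
* **Inter-animal variation**: every animal gets an independent multiplicative
  jitter *per band* (`1 + N(0, 0.006)`), shared across all its maps. A
  single global per-animal scale factor would cancel exactly under amide-II
  normalization and leave no biological variation at all; band-wise jitter
  is the smallest model that survives the pipeline. The default sd is set so
  that sample-level classification at the peak-effect day is
  near-deterministic — the regime a strong biomarker panel at its optimal
  read-out time should occupy — while remaining the main source of
  sample-level uncertainty.

Mice are assigned one dose for life; the train/test split is drawn at the
*animal* level (default 40% of mice per group to test), so no animal can
leak across the split.

## What the generator does not emulate

Water-vapour rotational fine structure, wavelength-dependent ATR penetration
depth, strain-specific spectra, spatial tissue morphology (pixels within a
map are exchangeable apart from dead pixels), and correlated pixel noise.
The last point matters for interpretation: because pixel noise is
independent, averaging ~100 QC-selected pixels per sample suppresses it
almost entirely, so synthetic off-peak days remain easier to classify than
real ones. Passing tests therefore demonstrate the correctness of the
pipeline's operations and the recoverability of the planted signal — not
in-vivo performance.

# Quality control

A pixel is kept iff

* amide SNR = (max absorbance in the amide-I window 1600–1700 cm^-1^) /
  (sd of absorbance in the quiet window 1800–2300 cm^-1^) ≥ 200, and
* amide / CO~2~ = (amide signal) / (max absorbance in 2300–2400 cm^-1^) ≥ 15.

The "amide signal" band and the "noise signature range" are package
decisions (configurable): amide I because it is the dominant protein band,
and 1800–2300 cm^-1^ because it is the spectrally quiet region between the
fingerprint and CO~2~ regions. Degenerate denominators pass rather than
reject — absence of contaminant or of noise is not a defect — while a dead
pixel fails the SNR test through its zero amide signal. Images retaining
more than 100 pixels are capped to the 100 quietest (lowest noise level),
with ties broken by (row, col) lexicographic order; images at or below the
cap keep everything; images retaining zero pixels are dropped from
classification and counted in the run manifest. QC runs on raw spectra by
default, before pretreatment, matching the acquisition-order workflow; a
post-pretreatment mode is a parameter away.

# Pretreatment

The five stages run in the order clip → fill → denoise → baseline →
normalize; each is a pure function of its input and parameters.

* **Clipping** keeps the closed interval [900, 3600] cm^-1^; the outer ends
  of the recorded range carry high variance.
* **Dead-pixel filling** flags pixels whose total absorbance falls below 10%
  of the image median (the threshold is a package decision) and replaces
  them with the mean spectrum of non-dead neighbours in a 5 × 5 window,
  truncated at the image boundary.
* **Median denoising** filters each wavenumber channel with a 5 × 5 spatial
  median, again truncated at the boundary (no padding); even-sized truncated
  corner windows use the mean-of-two-middle-values median, matching R's
  `median()`. Both spatial filters are compiled code with brute-force R
  oracles in the test suite.
* **Rubber-band baseline**: anchor wavenumbers {3600, 2750, 1800, 900}
  cm^-1^ are snapped to the spectrum minimum within ±25 cm^-1^; between
  consecutive support points the baseline follows the lower convex hull of
  the spectrum; the two axis endpoints are always supports so the baseline
  spans the whole spectrum. This replaces interactive "manual control
  points" with a deterministic, reproducible rule. The correction is exact
  (≡ 0) on convex spectra, annihilates straight lines to numerical
  precision, and never cuts above the spectrum at hull points.
* **Amide-II normalization** divides by the maximum in [1480, 1590] cm^-1^;
  pixels with a non-positive maximum cannot be normalized and are flagged
  invalid (zeroed and excluded downstream) rather than aborting the map.

Whether baseline correction should precede or follow the median filter is
not determinable in general; both orders are supported
(`baseline_before_denoise`), the default running the denoiser first. The
composition is idempotent in the absence of spatially varying per-pixel
structure; the median filter legitimately keeps reshaping genuinely varying
fields (e.g. per-pixel CO~2~ amplitudes) on repeated application.

# Second-derivative analysis

Savitzky–Golay differentiation uses window 5, polynomial order 3, derivative
order 2 — the standard setting for second-derivative band sharpening (a
window must exceed the polynomial order, which must be at least the
derivative order; the constructor enforces this). The derivative is taken
with respect to wavenumber using the physical axis spacing, so intensities
are comparable across clip settings; edge samples where the window is
truncated are returned as `NA` rather than extrapolated. The sign convention
is the spectroscopic one: an absorbance maximum appears as a second
derivative minimum at the same position.

Band read-outs report both conventions side by side: the *intensity at the
minimum* and the *peak-to-peak* statistic (mean of the two flanking local
maxima minus the minimum), the latter being more robust to residual
baseline. Band shifts are signed differences of detected minimum positions
between groups, searched within ±10 cm^-1^ of the nominal position; records
with no interior local minimum are flagged rather than fatal.

# Pixel pooling and outlier masking

Two region-selection arms mirror each other:

* **centre region**: the central 21 × 21 detector window (rows and columns
  53–73, 0-based, for the native 128 × 128 array);
* **embedding region**: pixels are embedded in 2-D using the 1500–1700
  cm^-1^ band (the dominant amide structure), and a pixel is rejected when
  its mean distance to its 20 nearest embedding neighbours exceeds the 99.5th
  percentile of that score — keeping over 99% of well-formed pixels. The
  embedding backend is pluggable behind a fixed contract (2-D, seeded,
  deterministic); the default is principal-component scores, which satisfies
  the contract exactly and reproducibly. The kNN-percentile rule is the
  package's outlier criterion: simple, deterministic given coordinates, and
  invariant to rigid motions of the embedding. Embedding runs on pretreated
  spectra.

# Classification

Features are the preprocessed absorbance values in [900, 1800] and
[2800, 3050] cm^-1^, concatenated per pixel (descending wavenumber within
each range), with no dimensionality reduction. Five families are supported:

* `lasso_lr`, `ridge_lr` — penalized logistic regressions (glmnet). The
  penalty is selected on a validation split carved from the *training
  samples* — selecting it on the test set, as is sometimes done, leaks; this
  is a deliberate protocol choice and the one place the package knowingly
  departs from common practice in this application area.
* `svm` — support vector machine (e1071), linear kernel by default,
  probability outputs for pixel scores.
* `fcnn` — a fully-connected net (hidden layers 128/32, ReLU), trained with
  Adam on binary cross-entropy.
* `cnn1d` — a small one-dimensional convolutional net: two strided
  convolution blocks (kernels 9 and 7, strides 3, channels 8 and 16, ReLU),
  global average pooling, one dense output. Small nets resist overfitting at
  pixel-pool scale; both nets are implemented in the package on base-R
  matrix operations with seeded initialization and shuffling, so identical
  seeds give identical fits.

LASSO doubles as the interpretable read-out: `lasso_selected_wavenumbers()`
returns the nonzero-coefficient wavenumbers ranked by |coefficient|. Note
that a band's discriminative signature includes its flanks — for a
*shifting* band especially, the strongest features sit beside the two centre
positions, not on them.

Sample-level calls are majority votes over the sample's pixel labels; the
positive-vote fraction is the sample's continuous score. An exact tie
predicts unexposed (conservative; configurable). A multi-class dose mode
(one-vs-rest) exists but is expected weak by construction under a flat
dose–response, and is reported as such.

# Evaluation

`stratified_report()` computes pixel and sample accuracy, balanced accuracy
(mean of sensitivity and specificity), the empirical ROC with trapezoid AUC
(ties grouped into single thresholds), and specificity at a fixed
sensitivity — reported at two pins, 0.9 and 0.99, because "specificity at
high sensitivity" is quoted under both conventions in this literature.
Strata: per dose (each dose's exposed samples pooled with *all* controls,
which are shared across dose strata) and per day. The permutation test
permutes labels at the sample level — never at the pixel level, which would
ignore within-sample correlation — and uses the add-one estimator
$p = (1 + \#\{\text{perm} \ge \text{obs}\})/(1 + B)$, so $p \in (0, 1]$.

# Numerical choices and problem sizes

Tolerances and scales used by the test-suite and the acceptance script are
package choices:

* unit fixtures run on 8–16 pixel-wide detectors with 1501-point axes
  (2 cm^-1^ spacing), small enough for brute-force oracles;
* the signal-recovery cohort is 10 mice per dose group (5 groups) at day 14,
  24 × 24 detectors, 751-point axes (4 cm^-1^ spacing, ~290 features);
* the null-calibration cohort is 10 mice per group, two groups, two days,
  12 × 12 detectors; 20 sample-level label permutations;
* the time-course cohort is 10 mice per group, two groups, five days,
  16 × 16 detectors;
* shift recovery is asserted to within one axis spacing; noise-free
  effect-size recovery to within 25% (Savitzky–Golay attenuation and band
  overlap account for a few percent).

Degenerate inputs are handled explicitly: empty band overlaps, single-point
windows, all-dead maps, single-class labels and unreachable sensitivities
raise informative errors; degenerate QC denominators and unnormalizable
pixels are handled pixel-wise without aborting a map.

# Known limitations

* The synthetic generator's noise independence overstates the benefit of
  within-sample pixel averaging (see above); day-stratified accuracies
  degrade less than they would in vivo.
* The embedding backend is linear; it fulfils the outlier-masking contract,
  but a non-linear manifold learner could reveal structure a PCA projection
  folds together. The backend is a plug-in point.
* Bruker OPUS files are out of scope; maps enter through the package's own
  on-disk format or are generated in memory.
* Inter-animal effect sizes and pixel-noise variances are not published
  quantities; the defaults here are documented modelling choices, and
  conclusions that depend on them should be re-checked across a range of
  `animal_effect_sd` and `noise_sd`.
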