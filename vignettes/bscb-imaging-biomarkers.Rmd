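---
title: "Imaging biomarkers of blood-spinal-cord-barrier disruption: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Imaging biomarkers of blood-spinal-cord-barrier disruption}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bscbmark)
```

This vignette is the package's account of the science it implements: the
models and their assumptions, the tunable parameters and why their
defaults are what they are, what the synthetic-data generators emulate
(and do not), and the numerical choices made where the design was open.
It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The measurement problem

In targeted EAE — a focal spinal-cord lesion induced by intraspinal
cytokine injection in pre-immunized mice — disease severity unfolds along
two coupled axes: endothelial barrier (BSCB) breakdown, visible acutely as
gadolinium leakage on DCE-MRI, and white-matter disintegration, visible
later as altered diffusion anisotropy on DTI. The package quantifies both
and links them to the ordinal 0–5 motor score (0 none, 0.5 weak tail
reflex, ..., 3 complete hind-limb paralysis, 5 moribund), with the specific
goal of treating acute barrier leakage as a *predictive* biomarker of later
demyelination.

## DTI quantification

### Signal model and tensor fit

Each voxel's signals follow the mono-exponential diffusion model
$S_k = S_0 \exp(-b\, g_k^\top D\, g_k)$ for unit gradient directions
$g_k$. `fit_tensor()` solves the log-linear system for the six unique
elements of $D$; with the default 6-direction dual-gradient scheme
($\pm x \pm y$, $\pm y \pm z$, $\pm x \pm z$, normalized) the system is
exactly determined and the "least-squares" fit is an exact inversion.
Units: eigenvalues are kept in μm²/ms (= 10⁻³ mm²/s) against b in s/mm²;
the default b = 4900 s/mm² follows the single-shot EPI cord protocol the
pipeline mirrors (the printed protocol value; stored as a scheme
parameter, never hard-coded).

Numerical choices:

* **Voxel validity.** Voxels with non-positive b0 or any non-positive
  diffusion-weighted signal cannot enter the log-linear system; they are
  flagged invalid and excluded from the maps rather than clamped, and the
  count is available from the fit object.
* **Eigenvalue clamping.** Noisy fits can produce small negative
  eigenvalues. They are clamped to 0 before FA/AD/RD (the alternative —
  excluding those voxels — was rejected because it would shrink the area
  denominators and bias the %area scores); the clamp count is reported.
* **Degenerate voxels.** FA is defined as 0 when all eigenvalues are 0.

### Noise robustness and the high-b regime

The phantom noise model is plain additive Gaussian noise on magnitudes
rather than Rician. At the noise levels the tests exercise the
distinction is negligible; the choice is visible in
`generate_dwi_phantom()` and documented here rather than hidden.

One property deserves honesty: at the protocol b-value of 4900 s/mm², the
white-matter diffusion-weighted signal along the least-attenuated mixed
directions is on the order of $e^{-5} S_0 \approx 0.007\,S_0$. Noise of
1% of $S_0$ is therefore ~150% of the available signal: a substantial
fraction of white-matter voxels draws a non-positive signal and is
excluded, and among survivors the log amplifies noise by $1/S$. The test
suite verifies that the fit meets a 5%-of-λ₁ mean-absolute-eigenvalue
error bound at b = 3000 s/mm² (where signal survives), and pins the
protocol-b behaviour with a wider seeded regression bound. This is a
property of the acquisition regime, not of the estimator: no amount of
per-voxel fitting recovers signal that is below the noise floor. Real
protocols compensate with multi-average acquisition, which the phantom
deliberately does not simulate.

### Threshold calibration and %area scores

The binarization thresholds (defaults FA ≥ 0.55, AD ≥ 1.4 μm²/ms,
RD ≤ 0.5 μm²/ms) are defined by calibration: the threshold is chosen so
that the binarized fraction of the cord cross-section equals the
white-matter area fraction at the injection level, ≈55%.
`calibrate_threshold()` implements this as the empirical quantile of
within-cord map values, resolved with the "lower" convention (the most
extreme threshold whose passing fraction still reaches the target) and
reports the achieved fraction; invalid voxels count toward the
denominator and can never pass, which keeps calibration and
`area_scores()` exactly consistent. Comparisons are inclusive (ties at
the threshold are positive). For multi-slice maps, scores are computed
per axial slice and averaged across the acquisition block (mirroring an
11-slice protocol centered on the injection level); pooled scoring is a
flag. Whether the original analysis calibrated on one slice or all, and
on naive or lesioned cords, is not stated anywhere we could consult; the
default here is the naive cord and per-slice averaging.

## DCE quantification

Relative enhancement per slice is $E(t) = (\bar S(t) - \bar S_{0^-}) /
\bar S_{0^-}$ from within-ROI means (cord ROIs are inputs; no automatic
segmentation). The Gd influx rate Kp-sc is the OLS slope of $E$ against
time over the post-injection scans — the linear-uptake (Patlak-like)
regime of a 10-minute window, consistent with enhancement reaching a
plateau by the sixth scan. The exact formula behind the originally cited
influx-rate method is not reproducible from the sources available here
(whether it normalizes by muscle or blood signal is unstated), so the
baseline-normalized slope is the documented stand-in, and the fitting
window is configurable for sensitivity analysis. Design choices:

* **Free intercept by default** — the first post-injection scan already
  carries intravascular signal; `through_origin = TRUE` gives the
  bolus-passes-instantaneously alternative.
* **Negative slopes are retained**, not clamped: clamping would bias the
  longitudinal normalization `relative_leakage()` (later timepoints
  expressed as % of the acute 7 DPI leakage).
* **Summation over slices** for whole-cord leakage is exact, making the
  score additive over slice sets — a tested invariant.

## Fluorescence vessel quantification

`segment_vessels()` implements the stated segmentation recipe — Canny
edge detection on the CD31 channel followed by hole filling — with three
numerical choices that measurement forced:

* **Hysteresis thresholds.** Fixed-percentile thresholds (e.g. 50th/90th
  of within-ROI gradient magnitude) admit a constant *fraction* of pixels
  regardless of contrast, so sparsely vascularized images drown in noise
  edges. The default is contrast-adaptive: the high threshold is Otsu's
  split of the within-ROI gradient-magnitude distribution, low = high/2.
  Both remain settable.
* **Smoothing scale.** Canny's Gaussian scale is σ = 1.5 px by default.
  The gradient ridge of a circular wall of radius r shifts inward by
  ≈ σ²/2r, so σ should stay below about half the thinnest wall thickness;
  at σ = 2 the bias exceeds 5% of area for vessels of radius ≤ 10 px.
* **Boundary convention.** The single-pixel Canny contour straddles the
  true boundary; keeping all of it dilates the mask by about half a pixel
  of boundary (≈ +5% area at r = 20), removing all of it erodes
  similarly. The implemented rule trims only contour pixels with ≥ 2
  exterior 4-neighbors (convex corners of the outline), centering the
  mask boundary on the gradient ridge; hole filling floods the background
  with 4-connectivity, the dual of the 8-connected contour.

"High-intensity" marker positivity is Otsu's threshold computed within
the relevant mask (the vessel mask for markers such as P-selectin; the
perivascular neighborhood for collagen) — a relative rule, so all areas
are invariant under positive intensity rescaling (tested). A constant
channel is positive only when its level exceeds zero, which covers the
degenerate all-zero and saturated cases. The perivascular neighborhood is
a disk dilation of the vessel mask by 10 px (whether the original MATLAB
routine dilated or used hand-drawn perivascular ROIs is unstated;
dilation is the reproducible choice), and the perivascular collagen area
subtracts the within-vessel collagen-positive area, floored at zero.
Components under 20 px are removed as speckle. Per-animal values are
means of (nominally three) images per cord region.

## The synthetic world

The generators state a world; their defaults are the documented
conditions, chosen once:

* **Cord phantom** — a disk cord (radius 24 px in a 64×64 image) whose
  outer annulus is white matter occupying exactly the target area
  fraction (55% by default; membership is resolved by radius ranking so
  the pixel-count fraction is exact to one pixel). Anatomical fidelity is
  a non-goal; only the area fraction matters for calibration. Tissue
  eigenvalues: WM (1.6, 0.45, 0.35) μm²/ms — FA ≈ 0.71, AD = 1.6,
  RD = 0.40, typical of healthy rodent cord white matter and on the
  passing side of all three default thresholds; GM (0.9, 0.7, 0.6) —
  FA ≈ 0.21, failing all three; lesion (1.0, 0.7, 0.6): lowered FA/AD,
  raised RD, the demyelination signature. The lesion is a contiguous
  dorsal subset of the white matter.
* **DCE phantom** — 11 slices, one pre-injection scan and six
  post-injection scans spanning 10 minutes; within-ROI intensity
  $S_0(1 + \mathrm{slope}\cdot t)$ plus voxel noise. Default slopes of
  0.005–0.055/min give whole-cord leakage of ~0.33/min, in the range
  where enhancement stays well below saturation.
* **Vessel phantom** — annular CD31 walls (thin = normal,
  thick = pathological), a marker channel covering a stated fraction of
  the filled vessel area (innermost pixels first, deterministic), and a
  collagen halo ring outside the wall. Foreground/background 1.0/0.1,
  noise ≤ 5% of foreground.
* **Cohort** — a single latent per-animal severity s ~ N(0,1) drives all
  observables: obs = mean + scale·(loading·s + noise·ε), with clinical
  score obtained by cut-pointing its latent variable onto the 0–5 ordinal
  scale (default cutpoints make the preset cohort span scores 0–3, the
  symptomatic range of this model). With loading² + noise² = 1 the
  population correlation between any two observables is the product of
  their loadings, so the EAE preset (`eae_coupling_preset()`)
  encodes its target correlation structure analytically:
  corr(gd@7, rd@14) = −0.699 and corr(gd@14, rd@21) = −0.877, i.e.
  population predictive power r² = 0.489 and 0.769, with Gd leakage
  decaying from its acute peak and the %areas declining over time.
  Couplings accept per-timepoint vectors (scalars recycle) precisely
  because a single loading per variable cannot express two different
  cross-timepoint couplings.

What a green test does *not* establish: the phantoms have no k-space
artifacts, motion, partial-volume mixing, eddy-current distortion, Rician
noise floors, or biological between-animal structure beyond one latent
factor; the cohort model is linear-Gaussian with a discretized score. The
generators validate the estimators' correctness and calibration, not the
acquisition physics.

## Statistics

* **Correlations** are Spearman by default (average ranks; clinical
  scores are heavily tied), Pearson for parameter–parameter pairs;
  p-values use the t approximation, with a permutation option (exact
  enumeration for n ≤ 7, seeded Monte Carlo above — full enumeration at
  n = 10 would need 3.6M permutations). Missing values are handled
  pairwise-complete. Strength bands for |r|: 0–0.2 very weak to
  negligible, 0.2–0.4 weak, 0.4–0.7 moderate, 0.7–1 strong; boundaries
  belong to the upper band. The same cuts label effect sizes r².
* **Standardized partial regression**: all variables z-scored, OLS fit,
  coefficients reported as β with two-sided p per coefficient; with one
  predictor β equals the Pearson r (a tested cross-operation identity).
  Collinearity is detected by the condition number of the standardized
  Gram matrix and reported with the offending predictor pair named.
* **Predictive power**: simple regression of %RD-negative area on Gd
  leakage 7 days earlier, paired within animal; r² is the reported
  predictive power. Under pairing shuffles its null expectation is
  1/(n−1), a tested sanity property.
* No multiple-testing correction is applied across correlation panels by
  default, matching per-panel reporting; `correlation_grid(holm = TRUE)`
  applies Holm. Group-difference tests (Mann–Whitney on scores, two-way
  ANOVA) exist only as a thin reporting utility.

## Pipeline and reproducibility

`run_pipeline()` executes simulate → DTI → DCE → IHC → statistics into a
fixed directory layout with a frozen `config.json`; one master seed fans
out to independent per-stage seeds (so a stage can be re-run in isolation
reproducibly), and identical config + seed yield byte-identical outputs —
an acceptance-tested property. Volumes are written as NIfTI-1 and vessel
channels as multi-page float TIFF through minimal built-in codecs (no
NIfTI/TIFF R package is assumed; the test suite cross-checks both codecs
against the reference Python readers). Configs are JSON.

## Known limitations

* The Kp-sc implementation is the baseline-normalized enhancement slope;
  if the original influx-rate normalization differed (e.g. by a blood or
  muscle reference), absolute leakage values shift by a scale factor,
  though the longitudinal percent normalization is unaffected.
* With exactly 6 directions the tensor fit has no redundancy: a single
  corrupted DW measurement invalidates the voxel rather than being
  down-weighted.
* At b = 4900 s/mm² and 1% additive noise, white-matter eigenvalue
  accuracy is signal-limited (see above).
* Vessel segmentation assumes approximately closed wall contours;
  heavily fragmented staining would need gap closing that the phantom
  world does not exercise.
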