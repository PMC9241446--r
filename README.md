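# bscbmark

Quantitative imaging biomarkers of blood–spinal-cord-barrier (BSCB)
disruption and white-matter integrity in targeted experimental autoimmune
encephalomyelitis (EAE), for preclinical MRI/histology groups who need a
tested, reusable pipeline rather than one-off image-analysis scripts.

Targeted EAE induces a focal inflammatory spinal-cord lesion in
pre-immunized mice. Longitudinal MRI of such lesions yields two families
of readouts:

* **DTI scalar maps.** From one b0 and K ≥ 6 diffusion-weighted images,
  the diffusion tensor D is fit per voxel from the log-linear model
  ln(S_k/S0) = −b·gₖᵀDgₖ, giving eigenvalues λ₁ ≥ λ₂ ≥ λ₃ and the maps
  FA (fractional anisotropy), AD = λ₁ (axial diffusivity) and
  RD = (λ₂+λ₃)/2 (radial diffusivity) — indices of white-matter, axonal
  and myelin integrity. Each map is binarized (FA ≥ 0.55, AD ≥ 1.4 μm²/ms,
  RD ≤ 0.5 μm²/ms by default) and reported as a percentage of the cord
  cross-section: %FA-positive, %AD-positive, %RD-negative area. The
  thresholds are calibrated so the binarized fraction equals the
  white-matter area fraction of the injection-site cord (≈55%);
  `calibrate_threshold()` performs this calibration on any map.
* **DCE-MRI Gd influx (Kp-sc).** After a gadolinium bolus, six serial
  T1-weighted scans over 10 min give per-slice relative enhancement
  E(t) = (S̄(t) − S̄₀)/S̄₀; the influx rate Kp-sc is the least-squares slope
  of E against t, and whole-cord **Gd leakage** is the sum of Kp-sc over
  slices — a BSCB-permeability score.

A third module quantifies vascular pathology from two-channel
fluorescence micrographs (CD31 vessel segmentation by Canny edge
detection + hole filling; P-selectin area within vessels; perivascular
collagen area by subtraction), and a statistics module links everything
longitudinally: per-timepoint Spearman/Pearson correlations with strength
bands, standardized partial regression of clinical score on the MRI
parameters, and an input–output prediction model whose effect size r²
(acute Gd leakage → %RD-negative area 7 days later) is read as predictive
power.

Because the original animal data are not public, the package ships seeded
generators (`generate_dwi_phantom()`, `generate_dce_series()`,
`generate_vessel_image()`, `generate_cohort()`) that produce phantoms and
cohorts with known ground truth, so every stage is testable end to end.

## Worked example

```r
library(bscbmark)

## 1. cord phantom with a demyelinating lesion in 25% of the white matter
spec    <- cord_phantom_spec(wm_fraction = 0.55, lesion_fraction = 0.25)
phantom <- generate_dwi_phantom(spec)
maps    <- compute_scalar_maps(fit_tensor(phantom$stack),
                               phantom$masks$cord, phantom$masks$wm)
area_scores(maps, dti_thresholds())
#> %FA positive area:  41.24
#> %AD positive area:  41.24
#> %RD negative area:  41.24

cal <- calibrate_threshold(maps$fa_map, maps$cord_mask, 0.55, ">=")
sprintf("calibrated FA threshold: %.3f (achieved fraction %.3f)",
        cal$threshold, cal$achieved_fraction)
#> "calibrated FA threshold: 0.265 (achieved fraction 0.550)"

## 2. DCE series: per-slice Kp-sc and summed Gd leakage
dce <- generate_dce_series(dce_phantom_spec(
  slice_slopes = seq(0.005, 0.055, 0.005), noise_sigma = 0.5, seed = 2))
score_dce(dce$series)
#> Gd leakage (sum Kp-sc over 11 slices): 0.3299 /min

## 3. longitudinal cohort statistics
coh <- generate_cohort(eae_cohort_preset(n_animals = 10, seed = 3))$table
correlate(coh, "gd_leakage", "clinical_score", dpi = 7)
#> spearman r = 0.753 (p = 0.01202, n = 10): strong correlation
predictive_power(coh, input_dpi = 14)
#> gd_leakage (14 DPI) -> pct_rd (21 DPI): r^2 = 0.852 (p = 0.0001396, n = 10): strong predictive power
```

The area scores read 41.24% because 25% of a 55% white-matter compartment
is lesioned (0.55 × 0.75 = 41.25%, up to one-pixel quantization): lesion
voxels fall below the FA/AD thresholds and above the RD threshold. The
cohort numbers come from the documented single-factor severity model, in
which acute Gd leakage is strongly coupled to clinical score and to the
later %RD-negative area (population r² = 0.77 for 14 → 21 DPI).

## Command-line pipeline

```sh
Rscript inst/cli/bscb-mark all --out run1 --seed 42
```

runs phantom simulation → DTI → DCE → IHC → statistics into `run1/`
(`maps/`, `curves/`, `ihc/`, `stats/`, `report.md`, frozen
`config.json`). Runs are byte-identical for a fixed config + seed. A JSON
config overrides any default (`--config cfg.json`); see
`default_run_config()`.

## Layout

* `R/phantom-*.R` — seeded generators for DWI/DCE/vessel phantoms and cohorts
* `R/dti.R`, `R/dce.R` — tensor fitting, maps, calibration, %areas; Kp-sc and leakage
* `R/ihc-*.R` — image primitives (Canny, hole filling, Otsu) and vessel quantification
* `R/stats.R` — correlations, standardized regression, prediction, strength bands
* `R/pipeline.R`, `inst/cli/bscb-mark` — end-to-end driver
* `vignettes/bscb-imaging-biomarkers.Rmd` — models, assumptions, numerical choices
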