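# cspws

Simulation and analysis for **chromatin-sensitive partial wave
spectroscopic (csPWS) nanocytology** — an optical statistical-nanosensing
approach that reads out chromatin packing structure from buccal (cheek)
cells as a candidate early-detection biomarker of lung cancer via field
carcinogenesis.

The package is aimed at method developers who need a fully synthetic,
end-to-end testbed for this class of pipelines: every stage, from the
chromatin density field to the cross-validated classifier, is simulated,
measurable and seeded.

## What it computes

Chromatin within packing domains shows mass fractal scaling, `N ∝ R^D`,
with the packing scaling `D` physically bounded in `[5/3, 3]`. csPWS does
not resolve domains (radii ~ 80 nm); it senses them statistically. With a
cell between glass and an index-matched liquid cover, the local refractive
index follows the local macromolecular density,

```
n(r) = n_media + α ρ(r),
```

and the interference of the glass/cell reference reflection with light
backscattered by RI fluctuations inside a coherence volume
(458 nm transverse × 2874 nm axial) produces a spectrum whose standard
deviation over wavelength, **Σ**, grows with the chromatin density
autocorrelation `B(r)` weighted by the instrument response. `B(r)` is a
modified power law with parameter `D_b`,
`B(r) = A (r/r_min)^(D_b−3)` on the fractal regime `[23, 334] nm`, and

```
D = 3 + ∂ log B(r) / ∂ log r
```

equals `D_b` inside the regime. The package implements:

* a seeded Gaussian-random-field simulator for chromatin density with this
  autocorrelation, a first-Born interference model of the microscope, and
  reference-normalized spectral cubes (`sample_chromatin_density()`,
  `simulate_interference_cube()`, `compute_sigma_image()`);
* the analytic forward map `Σ(D_b)` and its strictly monotone tabulated
  inversion, converting Σ images to per-pixel D images with clamp
  accounting (`sigma_from_db()`, `build_sigma_db_lookup()`,
  `sigma_image_to_d_image()`);
* a synthetic case–control cohort generator with hierarchical D structure,
  demographics and rendered nucleus D images (`cohort_spec()`,
  `generate_cohort()`);
* nucleus segmentation + shape QC, VGG16-layout convolutional features
  with per-patient multiple-instance mean/std aggregation
  (`segment_nuclei()`, `extract_cell_features()`, `aggregate_patient()`);
* random-forest recursive feature elimination (panel of 40), grid-tuned
  random-forest classification under stratified four-fold × five-repeat
  cross-validation (`rfe_select()`, `evaluate_repeated_cv()`);
* cohort statistics: control-normalized average nuclear D, type-II
  ANCOVA, subgroup regressions, age adjustment, ROC analysis and
  pack-year–stratified rank-sum tests (`patient_mean_d()`, `ancova_d()`,
  `average_d_auc()`, `packyear_subgroup_test()`).

A thin CLI (`exec/cspws`) exposes the stages as subcommands
(`simulate-cohort`, `dmap`, `features`, `classify`, `stats`, `run`).

## Worked example

```r
library(cspws)

## --- Forward simulation and D recovery ---
instrument <- make_default_instrument()
grid <- grid_spec(nx = 128, ny = 128, nz = 512, voxel_nm = 10)
template <- acf_model(d_b = 2.2)          # fixes amplitude scale and bounds

map <- build_sigma_db_lookup(template, instrument = instrument,
                             geometry = grid)
print(map)
#> Sigma-D_b lookup: 129 nodes on [1.6667, 3.0000], decreasing, Sigma in [0.00174, 0.0193]

cell <- anchored_acf_model(template, d_b = 2.4)
v <- sapply(1:3, function(s) {            # three simulated acquisitions
  cube <- simulate_cell_cube(cell, grid, instrument, seed = s)
  mean(compute_sigma_image(cube)$sigma^2)
})
rec <- invert_sigma_to_db(sqrt(mean(v)), map)
#> pooled Sigma: 0.0118
#> recovered d_b: 2.343 (true 2.4), clamped: FALSE
```

The lookup is *decreasing* here: with the autocorrelation amplitude
anchored at the fractal-regime midpoint, higher `D_b` moves correlation
mass away from the interferometric beat length, lowering Σ. The recovered
`d_b` for a single cell fluctuates at the ±0.05 level because each
coherence volume contributes only ~8 spectral degrees of freedom; the
validation suite pools more acquisitions.

```r
## --- Synthetic cohort, features, classification, statistics ---
spec <- cohort_spec(n_case = 15, n_control = 15, cells_per_patient = 10,
                    effect_delta_d = 0.45, seed = 11)
manifest <- generate_cohort(spec)
#> cohort manifest: 30 patients (15 case / 15 control), 300 cells

backbone <- backbone_spec(width_mult = 0.25, seed = 2)
features <- cohort_features(manifest, backbone, preproc_config(c(64, 64)))
cv <- evaluate_repeated_cv(features$features, features$labels,
                           cv_config(seed = 3))
print(cv)
#> repeated stratified CV (4 x 5): AUC 0.87 +/- 0.14, Se 45%, Sp 91%

patients <- patient_mean_d(manifest)
adjusted <- age_adjust(patients)
#> average-D AUC: 0.96 (age-adjusted 0.97)
print(ancova_d(patients))
#> ANCOVA (type-II F tests): normalized_d ~ group + age + pack_years + gender + race
#>        term     slope        F        p
#>       group  0.201000 40.76000 1.34e-06
#>         age -0.004080  5.48000 2.79e-02
#>  pack_years -0.000275  0.09343 7.63e-01
#>      gender -0.013700  0.13080 7.21e-01
#>       race -0.016500  0.17670 6.78e-01
```

This demonstration cohort has a deliberately large case effect
(ΔD = 0.45 ≈ 3 between-patient SDs) so the separation is visible at 30
patients; the group term dominates the ANCOVA, the injected negative age
trend appears with the expected sign, and the remaining demographics are
null, as constructed. The mean ± SD convention for CV metrics is the
dispersion across the 20 fold-by-repeat evaluations.

The methods vignette (`vignettes/cspws-methods.Rmd`) documents the
physical model, the realizable-process construction behind the field
synthesiser, the amplitude-anchoring that makes the Σ–D map invertible,
the cohort appearance model, and all numerical conventions.

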