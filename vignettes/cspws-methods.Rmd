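---
title: "Methods: simulating and inverting chromatin-sensitive PWS measurements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and inverting chromatin-sensitive PWS measurements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cspws)
```

## The measurement model

Chromatin-sensitive partial wave spectroscopic (csPWS) microscopy detects
sub-diffractional chromatin organization statistically. A cell sits between
glass and an index-matched liquid cover; the reference wave reflected at the
glass/cell interface interferes with light backscattered by refractive-index
(RI) fluctuations inside the nucleus. The per-pixel standard deviation of
the reference-normalized spectrum over wavelength, called Sigma, grows with
the RI fluctuations inside one coherence volume and therefore encodes the
chromatin packing statistics, even though none of the underlying structures
(roughly 20-300 nm) are resolved.

Three layers connect chromatin to the measurement in this package:

1. **Density to RI.** The local RI is linear in local macromolecular mass
   density, `n(r) = n_media + alpha * rho(r)`, with `alpha` the RI
   increment (default 0.18 mL/g, a value typical of biological
   macromolecules and nearly independent of their composition) and
   `n_media = 1.364` for the 95% ethanol cover. Both are configuration
   fields of the virtual instrument, never hard-coded constants.

2. **Chromatin statistics.** The mass-density autocorrelation `B(r)` is a
   modified power law controlled by the parameter `d_b`:
   `B(r) = A (r / r_min)^(d_b - 3)` inside the fractal regime
   `[r_min, r_max] = [23, 334] nm` (the instrument's length-scale
   sensitivity window), constant below `r_min`, with an exponential
   rolloff of decay length `r_max / 3` beyond `r_max`. The packing scaling
   is defined through the log-log derivative of the autocorrelation,
   `D = 3 + d log B / d log r`, evaluated by central differences (step
   1e-3 in log r) at the geometric midpoint of the fractal regime, where
   the pure power law makes the value scale-independent; inside the
   regime `D` coincides with `d_b` to about 1e-4.

3. **Optics.** A one-dimensional first-Born model per transverse pixel:
   the detected amplitude is the Fresnel reference `r_ref` plus the
   phase-weighted axial sum of RI fluctuations,
   `s(k) = i (k / 2 n_cell) \int dn(z) w(z) e^{2 i k z} dz`, inside a
   Gaussian axial window `w(z)` whose FWHM is the depth of field
   (2874 nm) and after transverse blurring with a Gaussian whose FWHM is
   the transverse coherence extent (458 nm, set by diffraction). The two
   coherence lengths are taken as instrument constants; deriving them
   from the numerical apertures alone is underdetermined, so they are
   configuration, not derivation. Reflectance is `|r_ref + s(k)|^2`,
   normalized by the blank-region reference `|r_blank|^2`. A homogeneous
   cell gives an exactly flat spectrum and Sigma = 0.

## A realizable random process for the chromatin field

The piecewise `B(r)` above is used verbatim for the packing-scaling
definition, but it is *not* a valid autocorrelation of any stationary 3-D
random field: its radial spectrum has negative lobes (up to roughly 16% of
spectral mass near `d_b = 3`), caused by the slope discontinuity at the
outer cutoff. Sampling a field "with ACF B" therefore requires a choice,
and the package makes it explicitly:

* the *process* autocorrelation (`process_acf()`) is an infinitely smooth
  analogue of `B`: a quartic knee replaces the hard plateau transition at
  `r_min`, and a logistic taper with the same asymptotic decay length
  replaces the exponential rolloff, centred at `(5/3) r_max` so it does
  not intrude into the fractal regime. Its log-log slope matches
  `d_b - 3` across the regime to better than 0.02;
* the radial spectrum of this process is computed by a sine-transform
  quadrature and any small negative residue (below ~1% over most of the
  `d_b` range, ~10% only at the extreme `d_b -> 3`) is clipped to zero.
  The clipped spectrum *defines* the process: the field synthesiser and
  the analytic Sigma map both consume it, so the forward and inverse
  routes can never drift apart.

Fields are synthesized spectrally on a periodic grid: complex white noise
is filtered by the square root of the sampled spectrum and one inverse FFT
produces the real-space field (one FFT per realization). Verified
properties: seeded bit-reproducibility, variance proportional to the model
amplitude, and a radially averaged empirical ACF whose log-log slope over
the fractal regime is within 0.15 of `d_b - 3` (averaged over five
realizations of a 128^3 grid at 10 nm voxels).

## The forward map Sigma(d_b) and its inversion

For a Gaussian field the expected sample variance of the normalized
spectrum over the wavelength grid is a quadratic form in the axial
covariance of the transversely blurred RI fluctuation. The package
evaluates it exactly: the blurred axial autocorrelation is obtained from
the clipped process spectrum (transverse modes are weighted by the squared
coherence-blur transfer function), assembled into the axial covariance
matrix, and contracted with the interferometric projection vectors
`w(z) sin(2 k_j z)` on the instrument's actual wavelength grid, including
the mean-subtraction term of the sample variance. Two geometries are
supported: a fine internal quadrature grid (the "continuous" instrument),
and the exact discrete, periodic geometry of a simulated cube — the latter
matches the Monte-Carlo mean of the simulator to a few tenths of a percent
and is what lookup tables for simulated data use. Within this model Sigma
scales exactly as the square root of the ACF amplitude.

**Amplitude anchoring.** The packing scaling measures the *slope* of the
autocorrelation, not its amplitude, so a one-parameter lookup family must
fix an amplitude convention. Holding the amplitude at `r_min` fixed makes
Sigma(d_b) non-monotone (flat near the lower physical bound), i.e. an
ill-posed inversion. The lookup family instead holds `B` fixed at the
geometric midpoint of the fractal regime — the same separation at which
`D` is evaluated — which decouples slope from amplitude and yields a
strictly monotone, well-conditioned map across the whole physical range
`[5/3, 3]`. In this instrument model the map is *decreasing*: with the
mid-regime amplitude pinned, raising `d_b` moves correlation mass away
from the interferometric beat length (about half the in-medium wavelength,
~100 nm separation scale) toward longer scales that the spectrally
averaged axial response suppresses. The direction is recorded in the
lookup object, and a non-monotone table raises an error rather than being
silently reordered. Out-of-range Sigma values clamp to the corresponding
endpoint and are *flagged*, never fatal, so noisy pixels cannot abort a
cohort run; `sigma = 0` therefore recovers the low-Sigma endpoint of the
map (`d_b = 3` under the decreasing direction).

The table uses 129 nodes and monotone piecewise-linear interpolation;
round-tripping `d_b -> Sigma -> d_b` across `[1.70, 2.95]` reproduces the
input to better than 1e-3, dominated by interpolation error.

**Noise of the per-pixel estimator.** A per-pixel Sigma is a standard
deviation over ~8 effective spectral degrees of freedom (set by the ratio
of the spectral span to the coherence width `1/sigma_z`), so single-pixel
inversions are noisy and, through the nonlinearity of the map, biased.
`sigma_image_to_d_image()` therefore offers mask-aware averaging of the
*squared* Sigma image over a configurable box before inversion; averaging
over a few transverse coherence areas suppresses both the noise and the
Jensen bias. Cube-level recovery in the tests pools the in-mask mean of
Sigma^2 before a single inversion, which is the minimum-variance version
of the same idea.

In end-to-end validation (four `d_b` values spanning 1.8-2.7, five seeds
each, 128 x 128 x 512 cubes at 10 nm voxels, cube counts per condition
chosen by a power analysis to equalize recovery noise), the recovered mean
in-mask D is unbiased within 0.05 and reproducible within 0.1 SD across
seeds, and the pooled simulated Sigma tracks the instrument-level analytic
map within 10%.

## The synthetic cohort generator

The generator emulates the statistical structure of a buccal-swab
case-control study. Defaults are the study conditions of the primary
cohort: 42 cases vs 40 controls, 30 cells per patient (about the count at
which the standard error of a patient's mean D becomes small relative to
the group difference), control age 59 +/- 11 vs case 67 +/- 12 years,
pack-years 35 +/- 26 vs 37 +/- 30, 49%/56% female, 80%/80% Caucasian, a
weak negative age trend of D (-0.006 per year), and 960 x 720 pixel D
images. The pixel pitch (250 nm, near the diffraction limit) is a
modeling choice of this package and is configurable.

Patient-level D follows a hierarchical truncated-normal model:
`baseline + effect * is_case + slope * (age - 59) + N(0, sd_patient^2)`,
truncated to the physical range [5/3, 3]; cell-level means add
`N(0, sd_cell^2)` with the same truncation. The dispersion defaults
(`baseline 2.15`, `effect 0.15`, `sd_patient 0.15`, `sd_cell 0.20`) were
calibrated once, before any test was written, so that the average-D ROC of
the default cohort sits in the mid-0.7 range reported for univariate
nuclear D — i.e. a realistically hard, not separable, problem. Note that
with the default age offset and negative age slope, the raw average-D AUC
is *depressed* by the age-group confound and age adjustment restores it;
the adjustment is therefore not performance-neutral here (the test suite
measures both sides against a normal-theory prediction). A cohort with
this much confounding cannot simultaneously show a near-zero effect of
age adjustment, so that behaviour is a property of these defaults, not a
defect of the adjustment.

**What the rendered images carry.** Every nucleus image is min-max
normalized before feature extraction, which removes all affine intensity
information — including a pure shift of mean D. The appearance model
therefore couples the packing-domain *texture* to the cell's mean D:
in-mask D is the cell mean plus a correlated Gaussian texture
(correlation length 750 nm) plus elevated-D domain patches (correlation
length 1.5 um, area fraction 25%) whose contrast grows linearly with
`(cell mean D - 5/3)`. Physically this encodes that higher packing
scaling manifests as more prominent, more heterogeneous packing domains.
Packing domains themselves (log-normal radii with mean 80 nm) are
sub-pixel at 250 nm sampling; they act by scaling the fine-texture
amplitude through the per-cell mean domain radius, not as resolved blobs.
Consequences worth keeping in mind: on a zero-effect cohort the groups are
exchangeable at every level (the null calibration of the classifier rests
on this), and on real data the conv-feature signal would ride on whatever
texture-D coupling biology provides, which this generator only imitates —
passing tests demonstrate pipeline correctness, not clinical performance.

The generator does not simulate shipment degradation, site batch effects,
optical aberrations, focus errors, cytoplasm/debris clutter, or
segmentation ambiguity; nuclei are clean ellipses with randomized
geometry.

## Feature extraction, aggregation and classification

Nucleus images are cropped to the mask bounding box, min-max normalized
([0, 1]; constant images map to 0.5), background-filled with 0 and
bilinearly resized (pixel-centre convention). The extractor is a
VGG16-layout stack of five 3x3 conv blocks with taps at the last
convolution of blocks 2-5 and per-channel global average pooling;
concatenation gives k = 1408 features at full width. Global average
pooling (rather than flattening full activation maps) keeps the
dimensionality fixed and the downstream selection tractable while
preserving the multi-scale block design; full flattening of the
activation maps remains available behind a configuration switch for
single-image work, but its dimensionality depends on the input size, so
cohort-level helpers require the pooled mode. Elementwise aggregation
makes the order of pooling and concatenation immaterial. Weights default to
seeded He-scaled Gaussians ("seeded_random"), making the whole feature
pipeline deterministic and self-contained; random conv projections
preserve the coarse texture statistics that the selection stage feeds on.
A pretrained mode is accepted but requires externally supplied weights.

Patient vectors are the multiple-instance mean/std aggregate: elementwise
mean and sample standard deviation over the patient's cells, concatenated
to length 2k. Selection is recursive feature elimination with a random
forest (drop the lowest-importance 20% per round until 40 remain — the
drop fraction is a convention of this implementation); the classifier is
a grid-tuned random forest (trees {100, 300, 500}, depth {unbounded, 8},
minimum node size {1, 3}), tied broken by grid order. Evaluation is
stratified four-fold cross-validation with five repeats; within every
training fold the panel is re-selected and the forest re-tuned
(leakage-free nested protocol; a "pooled" selection mode exists to mirror
protocols that select once on all data, and is not the default). The
operating point is the Youden-optimal threshold of the training scores;
summaries are mean +/- SD over the 20 evaluations, and that dispersion
convention is recorded in the result object.

## Cohort statistics

Average nuclear D per patient is the unweighted mean over kept cells,
divided by the control-group mean ("normalized by control", interpreted
as division by the mean, per site when several sites are present — a
documented convention, as is the choice of mean over median). ANCOVA is a
linear model with type-II F tests (the sum-of-squares type is a
convention of this implementation); collinear designs raise an error
naming the offending terms. Subgroup regressions are ordinary least
squares. Age adjustment subtracts the fitted control age trend.
Smoking-risk strata are split at 20 pack-years and compared by two-sided
Wilcoxon rank-sum tests, exact whenever the smaller group has at most 10
patients and no ties.

## Numerical choices and problem sizes

* Wavelength grid: 450-700 nm at 3 nm steps (84 samples), inclusive start.
* Quadratures: composite trapezoid on graded grids (fine near the origin);
  spectra are spline-interpolated on a 500-point log grid up to
  0.7 rad/nm.
* Voxels: 10 nm (the lower fractal bound must span at least two voxels);
  simulation boxes at least one upper fractal bound wide in every axis.
* Sample standard deviations use the n-1 denominator, package-wide.
* Float TIFFs store values affinely rescaled to [0, 1] with the transform
  recorded in the JSON sidecar (the storage layer's faithful float range),
  masks as 8-bit PNG.
* Test problem sizes: unit physics on 36 x 36 x 448 cubes; recovery on
  128 x 128 x 512 cubes with 8/5/3/2 cubes per seed for
  d_b = 1.8/2.1/2.4/2.7; cohort-scale classification tests use 80
  patients x 30 cells, a quarter-width backbone and 64 x 64 inputs. These
  sizes are the package's validation choices; the defaults users see
  (full-width backbone, 224 x 224 inputs, 129-node lookup) are stated
  above.

## Known limitations

* The optics is a scalar first-Born model with a separable Gaussian
  coherence weight; it preserves the reference-plus-backscatter physics
  and the monotone Sigma-D coupling the pipeline relies on, but it is not
  a vectorial solver, and absolute Sigma magnitudes inherit the chosen
  Born prefactor.
* The fluctuation amplitude default (0.02 g/mL RMS) keeps normalized
  spectral fluctuations at the few-percent level where the first-order
  expansion is accurate; much larger amplitudes would need the neglected
  second-order terms.
* `d_b` near 3 relies most on the clipped part of the spectrum and shows
  the largest (still small) recovery bias; `d_b` near 5/3 has the
  shallowest map slope and the largest variance.
* The cohort generator's dispersion parameters are plausibility
  calibrations, not fits to clinical data; no claim about real-world
  diagnostic performance follows from synthetic results.
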