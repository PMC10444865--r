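Package: cspws
Title: Chromatin-Sensitive Partial Wave Spectroscopic Nanocytology
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis tools for chromatin-sensitive partial
    wave spectroscopic (csPWS) nanocytology. Simulates chromatin mass-density
    fields with a prescribed power-law autocorrelation, propagates them
    through a first-Born interference model of the microscope to produce
    reference-normalized spectral cubes, and recovers the chromatin packing
    scaling D per pixel from the spectral standard deviation via a
    monotone lookup inversion. Includes a synthetic-cohort generator with
    patient-level covariates, nucleus segmentation and quality control,
    convolutional feature extraction with multiple-instance aggregation,
    recursive feature elimination with random-forest classification under
    repeated stratified cross-validation, and cohort statistics (control
    normalization, ANCOVA, subgroup regressions, age adjustment, ROC
    analysis).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    tiff,
    png,
    EBImage,
    ranger,
    car
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
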