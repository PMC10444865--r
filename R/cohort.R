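#' Synthetic cohort specification
#'
#' Defines the statistical structure of a simulated case-control cohort:
#' patient counts and demographics, the hierarchical model for nuclear
#' packing scaling D (case effect, age trend, between-patient and
#' between-cell dispersion), and the appearance model for rendered D
#' images. Defaults reproduce the Site-1 study conditions: 42 cases vs 40
#' controls, at least 30 cells per patient, control age 59 +/- 11 vs case
#' 67 +/- 12 years, pack-years 35 +/- 26 vs 37 +/- 30, 49%/56% female,
#' 80%/80% Caucasian, a weak negative age trend of D (-0.006 per year) and
#' 960 x 720 pixel D images.
#'
#' All D values are sampled from truncated normals so that patient and
#' cell means remain inside the physical range [5/3, 3].
#'
#' Because every nucleus image is min-max normalized before feature
#' extraction, a pure shift of mean D is affine-invariant and would be
#' invisible to convolutional features; the appearance model therefore
#' couples the packing-domain texture to the cell's mean D: cells with
#' higher D show a larger area fraction and contrast of elevated-D domain
#' patches, emulating the domain prominence seen in case cells.
#'
#' @param n_case,n_control Patient counts per group.
#' @param cells_per_patient Cells collected per patient (>= 2).
#' @param baseline_d Control-population mean nuclear D at the control mean
#'   age.
#' @param effect_delta_d Case minus control difference in mean nuclear D.
#' @param between_patient_sd,between_cell_sd D dispersion across patients
#'   and across cells within patient.
#' @param age_slope_per_year Linear age trend of true mean D (per year).
#' @param age_mean_control,age_sd_control,age_mean_case,age_sd_case Age
#'   distributions per group (years, truncated to [30, 95]).
#' @param pct_female_control,pct_female_case,pct_caucasian_control,pct_caucasian_case
#'   Demographic proportions.
#' @param packyear_mean_control,packyear_sd_control,packyear_mean_case,packyear_sd_case
#'   Smoking pack-years distributions (truncated at 0).
#' @param image_width,image_height Canvas size of rendered D images in
#'   pixels.
#' @param pixel_nm Image pixel pitch in nm.
#' @param texture_sd Standard deviation of the correlated intranuclear D
#'   texture.
#' @param texture_correlation_nm Correlation length of the fine D texture.
#' @param domain_patch_correlation_nm Correlation length of the elevated-D
#'   domain patches.
#' @param domain_area_fraction Area fraction of elevated-D domain patches.
#' @param domain_contrast_per_d Domain contrast gain per unit of
#'   (cell mean D - 5/3); links domain prominence to packing scaling.
#' @param domain_radius_mean_nm,domain_radius_sd_nm Mean and SD of the
#'   packing-domain radius distribution (log-normal); domains are
#'   sub-pixel and modulate texture amplitude rather than being resolved.
#' @param nucleus_semiaxis_px Range of the nucleus major semi-axis in
#'   pixels.
#' @param nucleus_axis_ratio Range of the minor/major axis ratio.
#' @param site Site label recorded in the manifest.
#' @param seed Master seed for cohort generation.
#' @return A `cspws_cohort_spec`.
#' @export
cohort_spec <- function(n_case = 42, n_control = 40,
                        cells_per_patient = 30,
                        baseline_d = 2.15,
                        effect_delta_d = 0.15,
                        between_patient_sd = 0.15,
                        between_cell_sd = 0.20,
                        age_slope_per_year = -0.006,
                        age_mean_control = 59, age_sd_control = 11,
                        age_mean_case = 67, age_sd_case = 12,
                        pct_female_control = 0.49, pct_female_case = 0.56,
                        pct_caucasian_control = 0.80, pct_caucasian_case = 0.80,
                        packyear_mean_control = 35, packyear_sd_control = 26,
                        packyear_mean_case = 37, packyear_sd_case = 30,
                        image_width = 960, image_height = 720,
                        pixel_nm = 250,
                        texture_sd = 0.15,
                        texture_correlation_nm = 750,
                        domain_patch_correlation_nm = 1500,
                        domain_area_fraction = 0.25,
                        domain_contrast_per_d = 0.25,
                        domain_radius_mean_nm = 80,
                        domain_radius_sd_nm = 40,
                        nucleus_semiaxis_px = c(16, 24),
                        nucleus_axis_ratio = c(0.65, 0.95),
                        site = "site1",
                        seed = 1) {
  stopifnot(n_case > 0, n_control > 0, cells_per_patient >= 2,
            baseline_d >= 5 / 3, baseline_d <= 3,
            between_patient_sd >= 0, between_cell_sd >= 0,
            image_width > 0, image_height > 0, pixel_nm > 0,
            domain_radius_mean_nm > 0,
            length(nucleus_semiaxis_px) == 2, length(nucleus_axis_ratio) == 2)
  obj <- as.list(environment())
  class(obj) <- "cspws_cohort_spec"
  obj
}

#' @export
print.cspws_cohort_spec <- function(x, ...) {
  cat(sprintf("cohort spec: %d cases / %d controls x %d cells, effect %+.3g D, site %s, seed %d\n",
              x$n_case, x$n_control, x$cells_per_patient, x$effect_delta_d,
              x$site, x$seed))
  invisible(x)
}

## Exact truncated-normal sampling by inverse-CDF.
.rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (any(sd == 0)) {
    out <- rep(pmin(pmax(mean, lower), upper), length.out = n)
    stats::runif(n)  # keep the RNG stream advancing uniformly
    return(out)
  }
  p_lo <- stats::pnorm(lower, mean, sd)
  p_hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(p_lo + stats::runif(n) * (p_hi - p_lo), mean, sd)
}

#' Sample one synthetic patient
#'
#' Draws demographics from the group's distributions and the patient's
#' true mean nuclear D from the hierarchical model
#' `baseline + effect * is_case + age_slope * (age - control mean age) +
#' N(0, between_patient_sd^2)`, truncated to [5/3, 3]. Uses the current
#' RNG state; seed at the cohort level for reproducibility.
#'
#' @param spec A `cspws_cohort_spec`.
#' @param group `"case"` or `"control"`.
#' @param patient_id Identifier stored in the record.
#' @return A one-row data frame (patient record).
#' @export
sample_patient <- function(spec, group = c("control", "case"),
                           patient_id = NA_character_) {
  group <- match.arg(group)
  case <- group == "case"
  age <- .rtruncnorm(1,
                     if (case) spec$age_mean_case else spec$age_mean_control,
                     if (case) spec$age_sd_case else spec$age_sd_control,
                     30, 95)
  pky <- .rtruncnorm(1,
                     if (case) spec$packyear_mean_case else spec$packyear_mean_control,
                     if (case) spec$packyear_sd_case else spec$packyear_sd_control,
                     0, Inf)
  gender <- if (stats::runif(1) < (if (case) spec$pct_female_case else spec$pct_female_control))
    "female" else "male"
  race <- if (stats::runif(1) < (if (case) spec$pct_caucasian_case else spec$pct_caucasian_control))
    "caucasian" else "other"
  mu <- spec$baseline_d +
    (if (case) spec$effect_delta_d else 0) +
    spec$age_slope_per_year * (age - spec$age_mean_control)
  true_d <- .rtruncnorm(1, mu, spec$between_patient_sd, 5 / 3, 3)
  data.frame(patient_id = patient_id, site = spec$site, group = group,
             age = age, pack_years = pky, gender = gender, race = race,
             true_mean_d = true_d, stringsAsFactors = FALSE)
}

#' Sample packing-domain radii
#'
#' Draws domain radii from the generator's log-normal distribution,
#' parameterized so that the distribution mean equals
#' `domain_radius_mean_nm` (default 80 nm) and its standard deviation
#' `domain_radius_sd_nm`.
#'
#' @param n Number of radii.
#' @param spec A `cspws_cohort_spec`.
#' @return Numeric vector of radii in nm.
#' @export
sample_domain_radii <- function(n, spec = cohort_spec()) {
  m <- spec$domain_radius_mean_nm
  s <- spec$domain_radius_sd_nm
  sdlog <- sqrt(log(1 + (s / m)^2))
  meanlog <- log(m) - sdlog^2 / 2
  stats::rlnorm(n, meanlog, sdlog)
}

## Correlated 2-D Gaussian texture with unit variance, periodic synthesis
## on the (padded) bounding box.
.texture_field <- function(nr, nc, corr_px) {
  qx <- .fft_freqs(nc, 1)
  qy <- .fft_freqs(nr, 1)
  h <- exp(-(corr_px^2 / 4) * outer(qy^2, qx^2, "+"))
  h[1, 1] <- 0  # remove DC so the texture is mean-free
  w <- matrix(complex(real = stats::rnorm(nr * nc),
                      imaginary = stats::rnorm(nr * nc)), nr, nc)
  x <- Re(stats::fft(h * w, inverse = TRUE)) / sqrt(nr * nc)
  sdx <- stats::sd(as.numeric(x))
  if (sdx == 0) matrix(0, nr, nc) else x / sdx
}

#' Render a synthetic nucleus D image
#'
#' Draws an elliptical nucleus mask at a randomized position, size and
#' orientation on the canvas and fills it with
#' `cell_mean_d` plus a correlated Gaussian texture and elevated-D domain
#' patches whose contrast grows with the cell's mean D. The per-cell mean
#' domain radius (drawn from the log-normal radius distribution) scales
#' the fine-texture amplitude, reflecting that sub-pixel domains modulate
#' the statistical texture rather than being resolved. Values are
#' truncated to [5/3, 3]; the background is `NaN`.
#'
#' @param cell_mean_d Target in-mask mean D, in [5/3, 3].
#' @param spec A `cspws_cohort_spec`.
#' @param seed Integer seed making the rendering reproducible.
#' @return A list with `d_image` (a `cspws_d_image`) and `mask`.
#' @export
render_d_image <- function(cell_mean_d, spec = cohort_spec(), seed = 1) {
  stopifnot(cell_mean_d >= 5 / 3, cell_mean_d <= 3)
  set.seed(seed)
  h <- spec$image_height
  w <- spec$image_width
  a <- stats::runif(1, spec$nucleus_semiaxis_px[1], spec$nucleus_semiaxis_px[2])
  b <- a * stats::runif(1, spec$nucleus_axis_ratio[1], spec$nucleus_axis_ratio[2])
  th <- stats::runif(1, 0, pi)
  margin <- ceiling(a) + 3
  cy <- stats::runif(1, margin, h - margin)
  cx <- stats::runif(1, margin, w - margin)
  bb_r <- ceiling(a) + 2
  rows <- max(1, floor(cy - bb_r)):min(h, ceiling(cy + bb_r))
  cols <- max(1, floor(cx - bb_r)):min(w, ceiling(cx + bb_r))
  yy <- outer(rows - cy, rep(1, length(cols)))
  xx <- outer(rep(1, length(rows)), cols - cx)
  u <- xx * cos(th) + yy * sin(th)
  v <- -xx * sin(th) + yy * cos(th)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  nr <- length(rows)
  nc <- length(cols)
  mean_radius <- mean(sample_domain_radii(200, spec))
  tex_amp <- spec$texture_sd * (mean_radius / spec$domain_radius_mean_nm)
  g1 <- .texture_field(nr, nc, spec$texture_correlation_nm / spec$pixel_nm)
  g2 <- .texture_field(nr, nc, spec$domain_patch_correlation_nm / spec$pixel_nm)
  f <- spec$domain_area_fraction
  thr <- stats::qnorm(1 - f)
  dom <- 1 / (1 + exp(-(g2 - thr) / 0.25))
  contrast <- spec$domain_contrast_per_d * (cell_mean_d - 5 / 3)
  patch <- cell_mean_d + tex_amp * g1 + contrast * (dom - mean(dom[inside]))
  patch <- pmin(pmax(patch, 5 / 3), 3)
  img <- matrix(NaN, h, w)
  mask <- matrix(FALSE, h, w)
  sub <- matrix(NaN, nr, nc)
  sub[inside] <- patch[inside]
  img[rows, cols] <- sub
  mask[rows, cols] <- inside
  list(d_image = d_image(img, mask), mask = mask)
}

#' Generate a labeled synthetic cohort
#'
#' Samples all patients and their per-cell mean D values under the
#' hierarchical model; optionally renders and writes every cell's D image
#' and nucleus mask to disk. Fully seeded: the same spec (including seed)
#' reproduces the manifest and images bit-for-bit.
#'
#' @param spec A `cspws_cohort_spec`.
#' @param dir Output directory for images and the manifest CSV; required
#'   when `write_images = TRUE`.
#' @param write_images Render each cell to a 32-bit float TIFF plus an
#'   8-bit PNG mask under `dir`.
#' @return A `cspws_manifest`: list with `patients` (one row per patient),
#'   `cells` (one row per cell: `patient_id`, `cell_id`, `cell_mean_d`,
#'   `render_seed`, and image/mask paths when written), `spec` and `seed`.
#' @export
generate_cohort <- function(spec = cohort_spec(), dir = NULL,
                            write_images = FALSE) {
  if (write_images && is.null(dir)) stop("dir is required when writing images")
  set.seed(spec$seed)
  groups <- c(rep("control", spec$n_control), rep("case", spec$n_case))
  ids <- sprintf("P%03d", seq_along(groups))
  patients <- do.call(rbind, lapply(seq_along(groups), function(i) {
    sample_patient(spec, groups[i], ids[i])
  }))
  n_cells <- spec$cells_per_patient
  cells <- do.call(rbind, lapply(seq_along(ids), function(i) {
    d <- .rtruncnorm(n_cells, patients$true_mean_d[i], spec$between_cell_sd,
                     5 / 3, 3)
    data.frame(patient_id = ids[i],
               cell_id = sprintf("%s_C%02d", ids[i], seq_len(n_cells)),
               cell_mean_d = d,
               render_seed = spec$seed + 100003L * i + seq_len(n_cells),
               stringsAsFactors = FALSE)
  }))
  cells$image_path <- NA_character_
  cells$mask_path <- NA_character_
  if (write_images) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (j in seq_len(nrow(cells))) {
      rend <- render_d_image(cells$cell_mean_d[j], spec, cells$render_seed[j])
      ip <- file.path(dir, paste0(cells$cell_id[j], "_D.tif"))
      mp <- file.path(dir, paste0(cells$cell_id[j], "_mask.png"))
      write_d_image(rend$d_image, ip)
      write_mask_png(rend$mask, mp)
      cells$image_path[j] <- ip
      cells$mask_path[j] <- mp
    }
  }
  man <- list(patients = patients, cells = cells, spec = spec,
              seed = spec$seed)
  class(man) <- "cspws_manifest"
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_manifest(man, dir)
  }
  man
}

#' @export
print.cspws_manifest <- function(x, ...) {
  cat(sprintf("cohort manifest: %d patients (%d case / %d control), %d cells\n",
              nrow(x$patients), sum(x$patients$group == "case"),
              sum(x$patients$group == "control"), nrow(x$cells)))
  invisible(x)
}

#' Generate a small spectral-cube cohort
#'
#' End-to-end bridge to the instrument model: for each cell, a chromatin
#' realization at that cell's D (amplitude anchored at the fractal-regime
#' midpoint) drives the interference simulator, producing a
#' reference-normalized spectral cube per cell. Intended for small counts;
#' the full-cube route costs seconds per cell.
#'
#' @param spec A `cspws_cohort_spec` (use small patient/cell counts).
#' @param instrument A `cspws_instrument`.
#' @param grid A `cspws_grid` for the per-cell simulation volume.
#' @param model_template A `cspws_acf` fixing amplitude scale and bounds.
#' @param dir Optional directory; when given, cubes and sidecars are
#'   written via [write_spectral_cube()].
#' @param manifest Optional pre-built `cspws_manifest` (e.g. an edited or
#'   reloaded cohort) to simulate from instead of generating one from
#'   `spec`.
#' @return A list with the cohort `manifest` and `cubes` (list of
#'   `cspws_cube`, or file paths when `dir` is given).
#' @export
generate_spectral_cohort <- function(spec, instrument, grid,
                                     model_template = acf_model(2.2),
                                     dir = NULL, manifest = NULL) {
  man <- if (is.null(manifest)) generate_cohort(spec) else manifest
  cubes <- vector("list", nrow(man$cells))
  names(cubes) <- man$cells$cell_id
  for (j in seq_len(nrow(man$cells))) {
    m <- anchored_acf_model(model_template, man$cells$cell_mean_d[j])
    cube <- simulate_cell_cube(m, grid, instrument,
                               seed = man$cells$render_seed[j])
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      p <- file.path(dir, paste0(man$cells$cell_id[j], "_cube.tif"))
      write_spectral_cube(cube, p,
                          sidecar = list(instrument = unclass(instrument),
                                         seed = man$cells$render_seed[j],
                                         true_d = man$cells$cell_mean_d[j]))
      cubes[[j]] <- p
    } else {
      cubes[[j]] <- cube
    }
  }
  list(manifest = man, cubes = cubes)
}
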