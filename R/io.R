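## On-disk formats: 32-bit float TIFF for images and spectral cubes with a
## JSON sidecar, 8-bit PNG for masks (255 = nucleus), CSV for manifests.
## The R tiff writer stores float samples faithfully only inside [0, 1],
## so values are affinely rescaled on write and the (offset, scale) pair is
## recorded in the sidecar; NaN background pixels are stored as 0 and
## reconstructed from the mask on read.

.sidecar_path <- function(path) paste0(path, ".json")

.write_sidecar <- function(path, sidecar) {
  jsonlite::write_json(sidecar, .sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
}

.read_sidecar <- function(path) {
  jsonlite::read_json(.sidecar_path(path), simplifyVector = TRUE)
}

.encode01 <- function(x) {
  fin <- is.finite(x)
  if (!any(fin)) return(list(x = x * 0, offset = 0, scale = 1))
  lo <- min(x[fin])
  hi <- max(x[fin])
  scale <- if (hi > lo) hi - lo else 1
  y <- (x - lo) / scale
  y[!fin] <- 0
  list(x = y, offset = lo, scale = scale)
}

#' Write / read a packing-scaling or Sigma image as 32-bit float TIFF
#'
#' Values are rescaled to [0, 1] for storage; the sidecar records the
#' affine transform, the mask, and any extra metadata. The mask is stored
#' as a companion 8-bit PNG next to the TIFF.
#'
#' @param img A `cspws_d_image` or `cspws_sigma_image`.
#' @param path Output TIFF path.
#' @param sidecar Named list of extra metadata for the JSON sidecar.
#' @return `path`, invisibly.
#' @export
write_d_image <- function(img, path, sidecar = list()) {
  vals <- if (inherits(img, "cspws_d_image")) img$d else img$sigma
  enc <- .encode01(vals)
  tiff::writeTIFF(enc$x, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  mask_path <- sub("\\.tiff?$", "_mask.png", path)
  if (identical(mask_path, path)) mask_path <- paste0(path, "_mask.png")
  write_mask_png(img$mask, mask_path)
  meta <- c(list(kind = class(img)[1], offset = enc$offset, scale = enc$scale,
                 mask_path = basename(mask_path)),
            if (inherits(img, "cspws_d_image"))
              list(clamped_fraction = img$clamped_fraction),
            sidecar)
  .write_sidecar(path, meta)
  invisible(path)
}

#' @rdname write_d_image
#' @export
read_d_image <- function(path) {
  meta <- .read_sidecar(path)
  x <- tiff::readTIFF(path)
  vals <- x * meta$scale + meta$offset
  mask <- read_mask_png(file.path(dirname(path), meta$mask_path))
  vals[!mask] <- NaN
  if (identical(meta$kind, "cspws_sigma_image")) {
    obj <- list(sigma = vals, mask = mask)
    class(obj) <- "cspws_sigma_image"
    obj
  } else {
    d_image(vals, mask,
            clamped_fraction = if (!is.null(meta$clamped_fraction))
              meta$clamped_fraction else 0)
  }
}

#' Write / read an 8-bit nucleus mask PNG (255 = nucleus)
#'
#' @param mask Logical matrix.
#' @param path PNG path.
#' @return `path` (write) or a logical matrix (read).
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3) x <- x[, , 1]
  x > 0.5
}

#' Write / read a spectral cube as multi-page 32-bit float TIFF
#'
#' One page per wavelength; the JSON sidecar records the wavelength grid,
#' the storage transform and caller metadata (instrument, seed, ...).
#'
#' @param cube A `cspws_cube`.
#' @param path Output TIFF path.
#' @param sidecar Named list of extra metadata.
#' @return `path`, invisibly.
#' @export
write_spectral_cube <- function(cube, path, sidecar = list()) {
  enc <- .encode01(cube$values)
  pages <- lapply(seq_along(cube$wavelengths_nm), function(i) enc$x[, , i])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  .write_sidecar(path, c(list(wavelengths_nm = cube$wavelengths_nm,
                              offset = enc$offset, scale = enc$scale),
                         sidecar))
  invisible(path)
}

#' @rdname write_spectral_cube
#' @export
read_spectral_cube <- function(path) {
  meta <- .read_sidecar(path)
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
  for (i in seq_along(pages)) {
    p <- pages[[i]]
    if (length(dim(p)) == 3) p <- p[, , 1]
    arr[, , i] <- p
  }
  arr <- arr * meta$scale + meta$offset
  spectral_cube(arr, as.numeric(meta$wavelengths_nm))
}

#' Write / read a cohort manifest
#'
#' Writes `manifest.csv` (one row per cell, joined with its patient's
#' covariates: patient_id, site, group, age, pack_years, gender, race,
#' cell_id, image_path, mask_path) plus `patients.csv` and a JSON snapshot
#' of the generating spec.
#'
#' @param manifest A `cspws_manifest`.
#' @param dir Output directory.
#' @return `dir` (write) or a `cspws_manifest` (read).
#' @export
write_manifest <- function(manifest, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  joined <- merge(manifest$cells,
                  manifest$patients[, c("patient_id", "site", "group", "age",
                                        "pack_years", "gender", "race")],
                  by = "patient_id", sort = FALSE)
  ord <- c("patient_id", "site", "group", "age", "pack_years", "gender",
           "race", "cell_id", "cell_mean_d", "render_seed", "image_path",
           "mask_path")
  utils::write.csv(joined[, ord], file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  utils::write.csv(manifest$patients, file.path(dir, "patients.csv"),
                   row.names = FALSE)
  jsonlite::write_json(unclass(manifest$spec),
                       file.path(dir, "cohort_spec.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(dir)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(dir) {
  cells_full <- utils::read.csv(file.path(dir, "manifest.csv"),
                                stringsAsFactors = FALSE)
  patients <- utils::read.csv(file.path(dir, "patients.csv"),
                              stringsAsFactors = FALSE)
  spec <- jsonlite::read_json(file.path(dir, "cohort_spec.json"),
                              simplifyVector = TRUE)
  class(spec) <- "cspws_cohort_spec"
  cells <- cells_full[, c("patient_id", "cell_id", "cell_mean_d",
                          "render_seed", "image_path", "mask_path")]
  man <- list(patients = patients, cells = cells, spec = spec,
              seed = spec$seed)
  class(man) <- "cspws_manifest"
  man
}
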