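#' Coherence-volume smoothing kernel
#'
#' Gaussian widths of the instrument smoothing applied to the chromatin
#' autocorrelation: the transverse width follows from the diffraction-
#' limited transverse coherence extent and the axial width from the depth
#' of field, both converted from FWHM to standard deviation.
#'
#' @param instrument A `cspws_instrument`.
#' @return A `cspws_kernel`: list with `transverse_sigma_nm` and
#'   `axial_sigma_nm`.
#' @export
smoothing_kernel <- function(instrument) {
  stopifnot(inherits(instrument, "cspws_instrument"))
  f <- 1 / (2 * sqrt(2 * log(2)))
  obj <- list(transverse_sigma_nm = instrument$transverse_coherence_nm * f,
              axial_sigma_nm = instrument$depth_of_field_nm * f)
  class(obj) <- "cspws_kernel"
  obj
}

## Blurred axial autocorrelation profile C_b(a): process ACF convolved with
## the transverse coherence Gaussian, evaluated at transverse lag zero, from
## the (clipped) radial spectrum:
##   C_b(a) = int dq_z cos(q_z a) psi(q_z),
##   psi(q_z) = 2 pi int q_t Phi(sqrt(q_t^2+q_z^2)) exp(-sig_t^2 q_t^2) dq_t / (2 pi)^2 ...
## (all constants folded so that C_b(0) equals the blurred variance).
.blurred_axial_acf <- function(phi, sig_t, a_nm) {
  qt <- c(seq(1e-5, 2e-3, by = 5e-5),
          exp(seq(log(2.05e-3), log(0.08), length.out = 260)))
  wqt <- .trapz_weights(qt)
  qz <- c(seq(0, 2e-3, by = 5e-5),
          exp(seq(log(2.05e-3), log(0.45), length.out = 380)))
  qmag <- sqrt(outer(qz^2, qt^2, "+"))
  ph <- matrix(phi(as.numeric(qmag)), nrow = length(qz))
  psi <- 2 * pi * as.numeric(ph %*% (qt * exp(-sig_t^2 * qt^2) * wqt))
  wqz <- .trapz_weights(qz)
  2 * as.numeric(cos(outer(a_nm, qz)) %*% (psi * wqz))
}

## Expected sample variance over the wavelength grid of the normalized
## spectrum, given an axial covariance Gamma (nz x nz) of the blurred RI
## fluctuation, axial positions z, window w, wavenumbers k and reflection
## constants. Returns sqrt(E[sample variance]) = Sigma.
.sigma_from_axial_cov <- function(gamma, z, w, vox, k, n_cell, r_ref, r_blank,
                                  alpha) {
  ts <- outer(z, k, function(z, k) sin(2 * k * z)) * w * vox
  cs <- crossprod(ts, gamma %*% ts) * alpha^2
  pref <- (2 * r_ref / r_blank^2) * (k / (2 * n_cell))
  cdi <- cs * outer(pref, pref)
  m <- length(k)
  ev <- (sum(diag(cdi)) - sum(cdi) / m) / (m - 1)
  sqrt(max(ev, 0))
}

#' Forward map: expected Sigma for a chromatin model
#'
#' Computes the expected spectral standard deviation of the reference-
#' normalized interference spectrum for a chromatin autocorrelation model
#' under the first-Born instrument model. The squared signal is a weighted
#' integral of the process autocorrelation over the coherence volume: the
#' transverse weight is the Gaussian coherence kernel, and the axial weight
#' combines the Gaussian depth-of-field window with the interferometric
#' phase factor induced by averaging over the source spectrum. Amplitude
#' scaling is exact: Sigma scales as the square root of the model
#' amplitude.
#'
#' With `geometry = NULL` the axial response is evaluated on a fine
#' internal quadrature grid (continuous instrument). Supplying a
#' `cspws_grid` evaluates the exact discrete, periodic response of a
#' simulated cube on that grid, which matches [simulate_cell_cube()] to
#' Monte-Carlo precision and is what lookup tables for simulated data
#' should use.
#'
#' @param model A `cspws_acf` model.
#' @param kernel A `cspws_kernel` (defaults to `smoothing_kernel(instrument)`).
#' @param instrument A `cspws_instrument`.
#' @param geometry Optional `cspws_grid` for discrete-geometry evaluation.
#' @param mean_crowding_g_ml Mean chromatin crowding (g/mL) fixing the mean
#'   cell refractive index.
#' @return Expected Sigma (dimensionless).
#' @export
sigma_from_db <- function(model, kernel = NULL, instrument,
                          geometry = NULL, mean_crowding_g_ml = 0.2) {
  stopifnot(inherits(model, "cspws_acf"), inherits(instrument, "cspws_instrument"))
  if (is.null(kernel)) kernel <- smoothing_kernel(instrument)
  if (model$amplitude == 0) return(0)
  sp <- process_spectrum(model)
  .sigma_from_spectrum(sp$phi, kernel, instrument, geometry, mean_crowding_g_ml)
}

.sigma_from_spectrum <- function(phi, kernel, instrument, geometry,
                                 mean_crowding_g_ml) {
  sig_t <- kernel$transverse_sigma_nm
  sig_z <- kernel$axial_sigma_nm
  n_cell <- instrument$n_media +
    instrument$ri_increment_alpha * mean_crowding_g_ml
  lam <- instrument_wavelengths(instrument)
  k <- 2 * pi * n_cell / lam
  r_ref <- .fresnel_r(instrument$n_glass, n_cell)
  r_blank <- .fresnel_r(instrument$n_glass, instrument$n_media)
  z0 <- instrument$axial_center_nm
  if (is.null(geometry)) {
    vox <- 8
    z <- seq(0, z0 + 3.5 * sig_z, by = vox)
    w <- exp(-(z - z0)^2 / (2 * sig_z^2))
    a <- z - z[1]
    cb <- .blurred_axial_acf(phi, sig_t, a)
    idx <- abs(outer(seq_along(z), seq_along(z), "-")) + 1L
    gamma <- matrix(cb[idx], length(z), length(z))
  } else {
    g <- geometry
    vox <- g$voxel_nm
    z <- (seq_len(g$nz) - 1) * vox
    w <- exp(-(z - z0)^2 / (2 * sig_z^2))
    gamma <- .discrete_axial_cov(phi, g, sig_t)
  }
  .sigma_from_axial_cov(gamma, z, w, vox, k, n_cell, r_ref, r_blank,
                        instrument$ri_increment_alpha)
}

## Exact circulant axial covariance (transverse lag zero) of the blurred
## field synthesized on a periodic grid: only transverse modes passed by
## the coherence blur contribute.
.discrete_axial_cov <- function(phi, grid, sig_t) {
  vox <- grid$voxel_nm
  qy <- .fft_freqs(grid$ny, vox)
  qx <- .fft_freqs(grid$nx, vox)
  qz <- .fft_freqs(grid$nz, vox)
  keep_y <- abs(qy) <= 6 / sig_t
  keep_x <- abs(qx) <= 6 / sig_t
  q2t <- outer(qy[keep_y]^2, qx[keep_x]^2, "+")
  h2 <- exp(-sig_t^2 * q2t)
  p <- vapply(qz, function(q) {
    sum(phi(sqrt(q2t + q^2)) * h2)
  }, numeric(1))
  p <- p * (2 * pi)^3 / vox^3 / (grid$ny * grid$nx)
  cax <- Re(stats::fft(p, inverse = TRUE)) / grid$nz
  idx <- abs(outer(seq_len(grid$nz), seq_len(grid$nz), "-"))
  idx <- pmin(idx, grid$nz - idx) + 1L
  matrix(cax[idx], grid$nz, grid$nz)
}

#' Tabulated monotone Sigma - D_b lookup
#'
#' Evaluates the forward map on an ascending `d_b` grid spanning the
#' physical packing-scaling range [5/3, 3] and verifies strict
#' monotonicity. The amplitude of each node model is anchored so that the
#' autocorrelation at the geometric midpoint of the fractal regime equals
#' that of the template (see [anchored_acf_model()]); a non-monotone table
#' is a configuration error and raises rather than being silently
#' reordered.
#'
#' @param model_template A `cspws_acf` fixing amplitude scale and fractal
#'   bounds.
#' @param kernel A `cspws_kernel` (defaults to the instrument's).
#' @param instrument A `cspws_instrument`.
#' @param grid_size Number of table nodes (>= 64).
#' @param geometry Optional `cspws_grid`, as in [sigma_from_db()].
#' @param mean_crowding_g_ml Mean chromatin crowding in g/mL.
#' @return A `cspws_sigma_db_map` with fields `d_b_grid`, `sigma_grid`,
#'   `packing_d_grid`, `direction` ("increasing" or "decreasing") and
#'   `provenance`.
#' @export
build_sigma_db_lookup <- function(model_template, kernel = NULL, instrument,
                                  grid_size = 129, geometry = NULL,
                                  mean_crowding_g_ml = 0.2) {
  stopifnot(grid_size >= 64)
  if (is.null(kernel)) kernel <- smoothing_kernel(instrument)
  d_grid <- seq(5 / 3, 3, length.out = grid_size)
  models <- lapply(d_grid, function(d) anchored_acf_model(model_template, d))
  sigma_grid <- vapply(models, function(m) {
    sigma_from_db(m, kernel, instrument, geometry, mean_crowding_g_ml)
  }, numeric(1))
  dd <- diff(sigma_grid)
  if (all(dd > 0)) {
    direction <- "increasing"
  } else if (all(dd < 0)) {
    direction <- "decreasing"
  } else {
    stop("forward map Sigma(d_b) is not strictly monotone over [5/3, 3]; ",
         "lookup configuration error")
  }
  packing_d_grid <- vapply(models, packing_d_from_acf, numeric(1))
  obj <- list(d_b_grid = d_grid, sigma_grid = sigma_grid,
              packing_d_grid = packing_d_grid, direction = direction,
              provenance = list(
                template = unclass(model_template),
                kernel = unclass(kernel),
                instrument = unclass(instrument),
                geometry = if (is.null(geometry)) NULL else unclass(geometry),
                mean_crowding_g_ml = mean_crowding_g_ml,
                anchor_nm = sqrt(model_template$r_min_nm * model_template$r_max_nm)))
  class(obj) <- "cspws_sigma_db_map"
  obj
}

#' Invert Sigma to the model parameter D_b
#'
#' Monotone piecewise-linear interpolation through the lookup table.
#' Sigma values outside the tabulated range clamp to the corresponding
#' endpoint `d_b` and are flagged, never fatal.
#'
#' @param sigma_value Numeric vector of Sigma values.
#' @param map A `cspws_sigma_db_map`.
#' @return A list with numeric `d_b` and logical `clamped`, both the length
#'   of `sigma_value`.
#' @export
invert_sigma_to_db <- function(sigma_value, map) {
  stopifnot(inherits(map, "cspws_sigma_db_map"))
  sg <- map$sigma_grid
  db <- map$d_b_grid
  if (map$direction == "decreasing") {
    sg <- rev(sg)
    db <- rev(db)
  }
  lo <- sg[1]
  hi <- sg[length(sg)]
  clamped <- !is.na(sigma_value) & (sigma_value < lo | sigma_value > hi)
  d_b <- stats::approx(sg, db, xout = pmin(pmax(sigma_value, lo), hi),
                       ties = "ordered")$y
  list(d_b = d_b, clamped = clamped)
}

#' Convert a Sigma image to a packing-scaling D image
#'
#' Inverts each in-mask pixel through the lookup and maps the recovered
#' `d_b` to packing scaling D via the autocorrelation derivative (inside
#' the fractal regime D and `d_b` coincide to ~1e-4). Because a per-pixel
#' Sigma is a standard deviation over few effective spectral degrees of
#' freedom, `smooth_radius_px` optionally averages the squared Sigma image
#' over a (2r+1)^2 neighbourhood (mask-aware) before inversion; choosing a
#' radius comparable to the transverse coherence extent suppresses the
#' noise-induced bias of the nonlinear inversion.
#'
#' @param sig A `cspws_sigma_image`.
#' @param map A `cspws_sigma_db_map`.
#' @param smooth_radius_px Box half-width (pixels) for variance smoothing;
#'   0 disables.
#' @return A `cspws_d_image`: list with `d` (matrix, `NaN` outside the
#'   mask), `mask`, and `clamped_fraction`.
#' @export
sigma_image_to_d_image <- function(sig, map, smooth_radius_px = 0) {
  stopifnot(inherits(sig, "cspws_sigma_image"),
            inherits(map, "cspws_sigma_db_map"))
  v <- sig$sigma^2
  if (smooth_radius_px > 0) {
    v <- .box_mean_masked(v, sig$mask, smooth_radius_px)
  }
  s <- sqrt(v[sig$mask])
  inv <- invert_sigma_to_db(s, map)
  d_vals <- stats::approx(map$d_b_grid, map$packing_d_grid, xout = inv$d_b,
                          rule = 2, ties = "ordered")$y
  d <- matrix(NaN, nrow(sig$sigma), ncol(sig$sigma))
  d[sig$mask] <- d_vals
  obj <- list(d = d, mask = sig$mask,
              clamped_fraction = mean(inv$clamped))
  class(obj) <- "cspws_d_image"
  obj
}

#' D image constructor
#'
#' @param d Matrix of packing scaling values (`NaN` outside mask).
#' @param mask Logical matrix.
#' @param clamped_fraction Fraction of in-mask pixels clamped by the
#'   inversion.
#' @return A `cspws_d_image`.
#' @export
d_image <- function(d, mask, clamped_fraction = 0) {
  mask <- .as_mask(mask)
  stopifnot(identical(dim(d), dim(mask)))
  obj <- list(d = d, mask = mask, clamped_fraction = clamped_fraction)
  class(obj) <- "cspws_d_image"
  obj
}

## Mask-aware box mean via summed-area tables; pixels outside the mask do
## not contribute and are returned as NaN.
.box_mean_masked <- function(x, mask, r) {
  x[!mask] <- 0
  num <- .box_sum(x, r)
  den <- .box_sum(mask * 1, r)
  out <- num / pmax(den, 1)
  out[!mask] <- NaN
  out[mask & den == 0] <- NaN
  out
}

.box_sum <- function(x, r) {
  nr <- nrow(x)
  nc <- ncol(x)
  cs <- apply(x, 2, cumsum)
  top <- rbind(matrix(0, r + 1, nc), cs)[seq_len(nr), , drop = FALSE]
  bot <- rbind(cs, matrix(rep(cs[nr, ], r), r, nc, byrow = TRUE))[r + seq_len(nr), , drop = FALSE]
  v <- bot - top
  cs2 <- t(apply(v, 1, cumsum))
  left <- cbind(matrix(0, nr, r + 1), cs2)[, seq_len(nc), drop = FALSE]
  right <- cbind(cs2, matrix(rep(cs2[, nc], r), nr, r))[, r + seq_len(nc), drop = FALSE]
  right - left
}

#' @export
print.cspws_sigma_db_map <- function(x, ...) {
  cat(sprintf("Sigma-D_b lookup: %d nodes on [%.4f, %.4f], %s, Sigma in [%.3g, %.3g]\n",
              length(x$d_b_grid), min(x$d_b_grid), max(x$d_b_grid),
              x$direction, min(x$sigma_grid), max(x$sigma_grid)))
  invisible(x)
}

#' Serialize / restore a Sigma-D_b lookup as JSON
#'
#' Writes the grids, monotone direction and the full parameter snapshot so
#' an inversion is reproducible from the artifact alone.
#'
#' @param map A `cspws_sigma_db_map`.
#' @param path JSON path.
#' @return `path` (write) or a `cspws_sigma_db_map` (read).
#' @export
write_sigma_db_map <- function(map, path) {
  stopifnot(inherits(map, "cspws_sigma_db_map"))
  jsonlite::write_json(unclass(map), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_sigma_db_map
#' @export
read_sigma_db_map <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$d_b_grid <- as.numeric(obj$d_b_grid)
  obj$sigma_grid <- as.numeric(obj$sigma_grid)
  obj$packing_d_grid <- as.numeric(obj$packing_d_grid)
  class(obj) <- "cspws_sigma_db_map"
  obj
}
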