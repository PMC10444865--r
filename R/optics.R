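#' Convert a chromatin density field to refractive index
#'
#' Applies the linear relation `n(r) = n_media + alpha * rho(r)` between
#' local macromolecular mass density and local refractive index.
#'
#' @param realization A `cspws_realization`.
#' @param instrument A `cspws_instrument` providing `n_media` and the
#'   refractive-index increment alpha.
#' @return An object of class `cspws_ri_field` with elements `values`
#'   (array `ny x nx x nz`) and `grid`.
#' @export
density_to_ri <- function(realization, instrument) {
  stopifnot(inherits(realization, "cspws_realization"),
            inherits(instrument, "cspws_instrument"))
  values <- instrument$n_media +
    instrument$ri_increment_alpha * realization$density
  obj <- list(values = values, grid = realization$grid)
  class(obj) <- "cspws_ri_field"
  obj
}

#' Construct a refractive-index field from raw values
#'
#' @param values Array `ny x nx x nz` of refractive indices.
#' @param grid The matching `cspws_grid`.
#' @return A `cspws_ri_field`.
#' @export
ri_field <- function(values, grid) {
  stopifnot(inherits(grid, "cspws_grid"),
            identical(dim(values), c(grid$ny, grid$nx, grid$nz)),
            all(is.finite(values)))
  obj <- list(values = values, grid = grid)
  class(obj) <- "cspws_ri_field"
  obj
}

#' Simulate a csPWS interference spectral cube
#'
#' One-dimensional first-Born model per transverse pixel: the detected
#' amplitude at wavenumber k is the Fresnel reflection `r_ref` at the
#' glass/cell interface plus the backscatter of the refractive-index
#' fluctuations within the axial collection window,
#' `s(k) = i (k / 2 n_cell) sum_z dn(z) w(z) exp(2 i k z) dz`,
#' with `k = 2 pi n_cell / lambda` the wavenumber inside the cell,
#' `w(z)` a Gaussian axial window of FWHM equal to the depth of field
#' centred `axial_center_nm` above the interface, and `dn` the fluctuation
#' field blurred transversely by a Gaussian of FWHM equal to the transverse
#' coherence extent. Detected reflectance is `|r_ref + s(k)|^2`; a
#' homogeneous cell therefore yields a wavelength-flat spectrum.
#'
#' @param ri A `cspws_ri_field`.
#' @param instrument A `cspws_instrument`.
#' @param transverse_blur Apply the transverse coherence blur before the
#'   axial summation (default TRUE; disable only for analytic checks).
#' @return A `cspws_cube`: list with `values` (array `ny x nx x n_lambda`
#'   of reflectance) and `wavelengths_nm`.
#' @export
simulate_interference_cube <- function(ri, instrument, transverse_blur = TRUE) {
  stopifnot(inherits(ri, "cspws_ri_field"), inherits(instrument, "cspws_instrument"))
  g <- ri$grid
  n_cell <- mean(ri$values)
  dn <- ri$values - n_cell
  if (transverse_blur) {
    sig_t <- instrument$transverse_coherence_nm / (2 * sqrt(2 * log(2)))
    dn <- .transverse_gaussian_blur(dn, g, sig_t)
  }
  lam <- instrument_wavelengths(instrument)
  k <- 2 * pi * n_cell / lam
  z <- (seq_len(g$nz) - 1) * g$voxel_nm
  sig_z <- instrument$depth_of_field_nm / (2 * sqrt(2 * log(2)))
  w <- exp(-(z - instrument$axial_center_nm)^2 / (2 * sig_z^2))
  ts <- outer(z, k, function(z, k) sin(2 * k * z)) * w * g$voxel_nm
  tc <- outer(z, k, function(z, k) cos(2 * k * z)) * w * g$voxel_nm
  dim(dn) <- c(g$ny * g$nx, g$nz)
  pref <- k / (2 * n_cell)
  ## s = i * pref * int dn e^{2ikz} => Re s = -pref * (dn %*% ts), Im s = pref * (dn %*% tc)
  re_s <- -sweep(dn %*% ts, 2, pref, "*")
  im_s <- sweep(dn %*% tc, 2, pref, "*")
  r_ref <- .fresnel_r(instrument$n_glass, n_cell)
  vals <- (r_ref + re_s)^2 + im_s^2
  dim(vals) <- c(g$ny, g$nx, length(lam))
  .cube(vals, lam)
}

## Periodic transverse Gaussian blur of a (ny x nx x nz) array, slice-wise
## in the Fourier domain.
.transverse_gaussian_blur <- function(x, grid, sigma_nm) {
  qy <- .fft_freqs(grid$ny, grid$voxel_nm)
  qx <- .fft_freqs(grid$nx, grid$voxel_nm)
  h <- exp(-sigma_nm^2 * outer(qy^2, qx^2, "+") / 2)
  out <- x
  for (iz in seq_len(grid$nz)) {
    out[, , iz] <- Re(stats::fft(stats::fft(x[, , iz]) * h, inverse = TRUE)) /
      (grid$ny * grid$nx)
  }
  out
}

.cube <- function(values, wavelengths_nm) {
  stopifnot(length(wavelengths_nm) == dim(values)[3],
            !is.unsorted(wavelengths_nm, strictly = TRUE))
  obj <- list(values = values, wavelengths_nm = wavelengths_nm)
  class(obj) <- "cspws_cube"
  obj
}

#' Spectral cube constructor
#'
#' @param values Array `ny x nx x n_lambda` of non-negative reflectance.
#' @param wavelengths_nm Strictly increasing wavelength vector.
#' @return A `cspws_cube`.
#' @export
spectral_cube <- function(values, wavelengths_nm) {
  if (any(values < 0, na.rm = TRUE)) stop("reflectance values must be >= 0")
  .cube(values, wavelengths_nm)
}

#' Reference spectral cube from a blank slide region
#'
#' The reference wave is acquired at the glass / cover-media interface of a
#' blank region, so its reflectance is the flat Fresnel value
#' `((n_glass - n_media) / (n_glass + n_media))^2` at every pixel and
#' wavelength.
#'
#' @param instrument A `cspws_instrument`.
#' @param ny,nx Transverse dimensions of the cube to produce.
#' @return A `cspws_cube`.
#' @export
simulate_reference_cube <- function(instrument, ny, nx) {
  lam <- instrument_wavelengths(instrument)
  r0 <- .fresnel_r(instrument$n_glass, instrument$n_media)
  .cube(array(r0^2, c(ny, nx, length(lam))), lam)
}

#' Normalize a cube by the reference wave
#'
#' Elementwise ratio of the raw cube to the reference cube.
#'
#' @param raw,reference `cspws_cube` objects on identical wavelength grids;
#'   the reference must be strictly positive.
#' @return A `cspws_cube` of normalized spectra.
#' @export
reference_normalize <- function(raw, reference) {
  stopifnot(inherits(raw, "cspws_cube"), inherits(reference, "cspws_cube"))
  if (!isTRUE(all.equal(raw$wavelengths_nm, reference$wavelengths_nm))) {
    stop("wavelength grids of raw and reference cubes differ")
  }
  if (!identical(dim(raw$values), dim(reference$values))) {
    stop("cube dimensions differ")
  }
  if (any(reference$values <= 0)) stop("reference cube must be strictly positive")
  .cube(raw$values / reference$values, raw$wavelengths_nm)
}

#' Spectral standard deviation image (Sigma)
#'
#' Per-pixel sample standard deviation (n - 1 denominator) of the
#' normalized interference spectrum over wavelength; `NaN` outside the
#' nucleus mask.
#'
#' @param cube A `cspws_cube` of reference-normalized spectra.
#' @param mask Logical matrix `ny x nx`; TRUE inside the nucleus. Defaults
#'   to the full frame.
#' @return A `cspws_sigma_image`: list with `sigma` (matrix) and `mask`.
#' @export
compute_sigma_image <- function(cube, mask = NULL) {
  stopifnot(inherits(cube, "cspws_cube"))
  d <- dim(cube$values)
  if (d[3] < 3) stop("need at least 3 wavelengths to estimate Sigma")
  if (is.null(mask)) mask <- matrix(TRUE, d[1], d[2])
  mask <- .as_mask(mask)
  if (!identical(dim(mask), d[1:2])) stop("mask dimensions do not match cube")
  x <- cube$values
  dim(x) <- c(d[1] * d[2], d[3])
  mu <- rowMeans(x)
  v <- (rowSums(x * x) - d[3] * mu * mu) / (d[3] - 1)
  sg <- sqrt(pmax(v, 0))
  dim(sg) <- d[1:2]
  sg[!mask] <- NaN
  obj <- list(sigma = sg, mask = mask)
  class(obj) <- "cspws_sigma_image"
  obj
}

.as_mask <- function(mask) {
  if (is.logical(mask)) {
    m <- mask
  } else {
    m <- mask > 0
  }
  storage.mode(m) <- "logical"
  m
}

#' Fused cell simulation: model to normalized spectral cube
#'
#' Equivalent to [sample_chromatin_density()] followed by
#' [density_to_ri()], [simulate_interference_cube()] and
#' [reference_normalize()], but performs the synthesis, transverse
#' coherence blur and axial projection in a single spectral pass. Used by
#' cohort-scale simulations where the composed route would recompute
#' identical FFTs.
#'
#' @inheritParams sample_chromatin_density
#' @param instrument A `cspws_instrument`.
#' @param synthesis_amplitude Optional precomputed synthesis amplitude (from
#'   repeated simulation at the same model and grid); when supplied it must
#'   come from the same (model, grid).
#' @return A reference-normalized `cspws_cube`.
#' @export
simulate_cell_cube <- function(model, grid, instrument, seed,
                               mean_crowding_g_ml = 0.2,
                               synthesis_amplitude = NULL) {
  stopifnot(inherits(model, "cspws_acf"), inherits(grid, "cspws_grid"),
            inherits(instrument, "cspws_instrument"))
  if (grid$voxel_nm > model$r_min_nm / 2) {
    stop("voxel_nm does not resolve the lower fractal bound")
  }
  sig_t <- instrument$transverse_coherence_nm / (2 * sqrt(2 * log(2)))
  if (is.null(synthesis_amplitude)) {
    synthesis_amplitude <- .synthesis_amplitude(model, grid)
  }
  qy <- .fft_freqs(grid$ny, grid$voxel_nm)
  qx <- .fft_freqs(grid$nx, grid$voxel_nm)
  h <- exp(-sig_t^2 * outer(qy^2, qx^2, "+") / 2)
  amp <- synthesis_amplitude * array(rep(h, grid$nz),
                                     c(grid$ny, grid$nx, grid$nz))
  set.seed(seed)
  n <- grid$ny * grid$nx * grid$nz
  w <- array(complex(real = stats::rnorm(n), imaginary = stats::rnorm(n)),
             dim = dim(amp))
  dn_b <- Re(stats::fft(amp * w, inverse = TRUE)) / sqrt(n) *
    instrument$ri_increment_alpha
  n_cell <- instrument$n_media +
    instrument$ri_increment_alpha * mean_crowding_g_ml
  lam <- instrument_wavelengths(instrument)
  k <- 2 * pi * n_cell / lam
  z <- (seq_len(grid$nz) - 1) * grid$voxel_nm
  sig_z <- instrument$depth_of_field_nm / (2 * sqrt(2 * log(2)))
  wz <- exp(-(z - instrument$axial_center_nm)^2 / (2 * sig_z^2))
  ts <- outer(z, k, function(z, k) sin(2 * k * z)) * wz * grid$voxel_nm
  tc <- outer(z, k, function(z, k) cos(2 * k * z)) * wz * grid$voxel_nm
  dim(dn_b) <- c(grid$ny * grid$nx, grid$nz)
  pref <- k / (2 * n_cell)
  re_s <- -sweep(dn_b %*% ts, 2, pref, "*")
  im_s <- sweep(dn_b %*% tc, 2, pref, "*")
  r_ref <- .fresnel_r(instrument$n_glass, n_cell)
  r_blank <- .fresnel_r(instrument$n_glass, instrument$n_media)
  vals <- ((r_ref + re_s)^2 + im_s^2) / r_blank^2
  dim(vals) <- c(grid$ny, grid$nx, length(lam))
  .cube(vals, lam)
}
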