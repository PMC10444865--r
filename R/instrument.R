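#' Instrument configuration for the csPWS forward model
#'
#' Bundles the illumination/collection geometry, spectral sampling and
#' refractive-index constants of the virtual microscope. Cells are imaged
#' between a glass slide and a 95% ethanol liquid cover whose refractive
#' index nearly matches the cell, so the dominant reference reflection
#' arises at the glass/cell interface.
#'
#' @param na_illumination Illumination numerical aperture.
#' @param na_collection Collection numerical aperture.
#' @param wavelength_min_nm,wavelength_max_nm,wavelength_step_nm Spectral
#'   sampling in nm. The default 450-700 nm range at 3 nm steps (the
#'   tunable-filter bandwidth) yields 84 samples.
#' @param n_media Refractive index of the liquid cover (95% ethanol).
#' @param n_glass Refractive index of the slide.
#' @param ri_increment_alpha Refractive-index increment alpha in mL/g
#'   relating macromolecular mass density to refractive index,
#'   n(r) = n_media + alpha * rho(r). Nearly independent of macromolecular
#'   composition.
#' @param transverse_coherence_nm Transverse extent (FWHM) of the coherence
#'   volume formed by diffraction in the transverse plane.
#' @param depth_of_field_nm Axial depth of field (FWHM of the axial
#'   collection window).
#' @param axial_center_nm Depth below which the axial collection window is
#'   centred, measured from the glass/cell interface. Defaults to one depth
#'   of field.
#'
#' @return An object of class `cspws_instrument`.
#' @export
instrument_config <- function(na_illumination = 0.6,
                              na_collection = 0.8,
                              wavelength_min_nm = 450,
                              wavelength_max_nm = 700,
                              wavelength_step_nm = 3,
                              n_media = 1.364,
                              n_glass = 1.517,
                              ri_increment_alpha = 0.18,
                              transverse_coherence_nm = 458,
                              depth_of_field_nm = 2874,
                              axial_center_nm = depth_of_field_nm) {
  stopifnot(na_illumination > 0,
            na_illumination <= na_collection,
            na_collection < n_media,
            wavelength_min_nm < wavelength_max_nm,
            wavelength_step_nm > 0,
            transverse_coherence_nm > 0,
            depth_of_field_nm > 0,
            axial_center_nm > 0,
            ri_increment_alpha > 0)
  obj <- list(na_illumination = na_illumination,
              na_collection = na_collection,
              wavelength_min_nm = wavelength_min_nm,
              wavelength_max_nm = wavelength_max_nm,
              wavelength_step_nm = wavelength_step_nm,
              n_media = n_media,
              n_glass = n_glass,
              ri_increment_alpha = ri_increment_alpha,
              transverse_coherence_nm = transverse_coherence_nm,
              depth_of_field_nm = depth_of_field_nm,
              axial_center_nm = axial_center_nm)
  class(obj) <- "cspws_instrument"
  obj
}

#' Default csPWS instrument
#'
#' Returns the instrument configuration used throughout: incidence NA 0.6,
#' collection NA 0.8, 450-700 nm spectral range, 458 nm transverse coherence
#' extent and 2874 nm depth of field.
#'
#' @return A `cspws_instrument` object.
#' @export
make_default_instrument <- function() {
  instrument_config()
}

#' Wavelength grid of an instrument
#'
#' @param instrument A `cspws_instrument`.
#' @return Numeric vector of sampled wavelengths in nm.
#' @export
instrument_wavelengths <- function(instrument) {
  seq(instrument$wavelength_min_nm, instrument$wavelength_max_nm,
      by = instrument$wavelength_step_nm)
}

#' @export
print.cspws_instrument <- function(x, ...) {
  cat("csPWS instrument\n")
  cat(sprintf("  NA %g/%g, %g-%g nm (step %g), n_media %g, n_glass %g\n",
              x$na_illumination, x$na_collection,
              x$wavelength_min_nm, x$wavelength_max_nm, x$wavelength_step_nm,
              x$n_media, x$n_glass))
  cat(sprintf("  alpha %g mL/g, coherence %g nm (transverse) x %g nm (axial)\n",
              x$ri_increment_alpha, x$transverse_coherence_nm,
              x$depth_of_field_nm))
  invisible(x)
}

#' Voxel grid specification
#'
#' Defines the sampling grid for simulated chromatin volumes. The first
#' axial voxel sits at the glass/cell interface (z = 0).
#'
#' @param nx,ny,nz Voxel counts along x, y (transverse) and z (axial).
#' @param voxel_nm Isotropic voxel pitch in nm.
#' @return An object of class `cspws_grid`.
#' @export
grid_spec <- function(nx, ny, nz, voxel_nm) {
  stopifnot(nx >= 2, ny >= 2, nz >= 2, voxel_nm > 0)
  obj <- list(nx = as.integer(nx), ny = as.integer(ny), nz = as.integer(nz),
              voxel_nm = voxel_nm)
  class(obj) <- "cspws_grid"
  obj
}

#' @export
print.cspws_grid <- function(x, ...) {
  cat(sprintf("csPWS grid: %d x %d x %d voxels at %g nm (%g x %g x %g nm)\n",
              x$nx, x$ny, x$nz, x$voxel_nm,
              x$nx * x$voxel_nm, x$ny * x$voxel_nm, x$nz * x$voxel_nm))
  invisible(x)
}

## Interface Fresnel amplitude reflection coefficient (normal incidence).
.fresnel_r <- function(n1, n2) (n1 - n2) / (n1 + n2)
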