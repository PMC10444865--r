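#' Sample a chromatin mass-density field
#'
#' Draws a stationary Gaussian random field whose autocorrelation follows
#' the model's realizable process ACF ([process_acf()]), by spectral
#' synthesis: the (clipped, non-negative) radial spectrum is sampled on the
#' periodic grid and filters complex white noise, and one inverse FFT
#' produces the real-space field. The returned density is the zero-mean
#' fluctuation plus the mean chromatin crowding.
#'
#' The synthesis is periodic; samples separated by more than half the box
#' are correlated through the nearest periodic image, which is negligible
#' whenever the box extent comfortably exceeds the correlation range (the
#' constructor enforces extent >= the upper fractal bound on every axis).
#'
#' @param model A `cspws_acf` model.
#' @param grid A `cspws_grid`. The voxel pitch must resolve the lower
#'   fractal bound with at least two voxels.
#' @param seed Integer seed; the same (model, grid, seed) always yields a
#'   bit-identical field.
#' @param mean_crowding_g_ml Mean macromolecular crowding in g/mL added to
#'   the fluctuation field.
#' @return An object of class `cspws_realization` with elements `density`
#'   (array `ny x nx x nz`, g/mL), `grid`, `model`, `seed`,
#'   `mean_crowding_g_ml`.
#' @export
sample_chromatin_density <- function(model, grid, seed,
                                     mean_crowding_g_ml = 0.2) {
  stopifnot(inherits(model, "cspws_acf"), inherits(grid, "cspws_grid"))
  if (grid$voxel_nm > model$r_min_nm / 2) {
    stop("voxel_nm = ", grid$voxel_nm,
         " nm does not resolve the lower fractal bound (need <= ",
         model$r_min_nm / 2, " nm)")
  }
  ext <- c(grid$nx, grid$ny, grid$nz) * grid$voxel_nm
  if (any(ext < model$r_max_nm)) {
    stop("grid extent (", paste(ext, collapse = " x "),
         " nm) is smaller than the upper fractal bound ",
         model$r_max_nm, " nm; enlarge the grid")
  }
  if (model$amplitude == 0) {
    fl <- array(0, c(grid$ny, grid$nx, grid$nz))
  } else {
    amp <- .synthesis_amplitude(model, grid)
    set.seed(seed)
    n <- grid$ny * grid$nx * grid$nz
    w <- array(complex(real = stats::rnorm(n), imaginary = stats::rnorm(n)),
               dim = dim(amp))
    fl <- Re(stats::fft(amp * w, inverse = TRUE)) / sqrt(n)
  }
  obj <- list(density = fl + mean_crowding_g_ml, grid = grid, model = model,
              seed = seed, mean_crowding_g_ml = mean_crowding_g_ml)
  class(obj) <- "cspws_realization"
  obj
}

## Fourier-domain synthesis amplitude sqrt(s_k) for a grid (ny x nx x nz),
## with s_k = Phi(|q_k|) (2 pi)^3 / voxel^3 so that the circulant ACF is the
## Riemann sampling of the continuous spectrum.
.synthesis_amplitude <- function(model, grid) {
  sp <- process_spectrum(model)
  vox <- grid$voxel_nm
  qy <- .fft_freqs(grid$ny, vox)
  qx <- .fft_freqs(grid$nx, vox)
  qz <- .fft_freqs(grid$nz, vox)
  q2t <- outer(qy^2, qx^2, "+")
  qmag <- sqrt(outer(q2t, qz^2, "+"))
  s <- sp$phi(as.numeric(qmag)) * (2 * pi)^3 / vox^3
  dim(s) <- c(grid$ny, grid$nx, grid$nz)
  sqrt(s)
}

## Angular spatial frequencies (rad/nm) in FFT order for n samples.
.fft_freqs <- function(n, voxel_nm) {
  m <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)[1:n]
  2 * pi * m / (n * voxel_nm)
}

#' Radially averaged empirical autocorrelation of a realization
#'
#' Estimates the autocorrelation of the density fluctuations by the
#' Wiener-Khinchin relation on the periodic grid and averages it over
#' spherical shells. Used to verify that sampled fields reproduce the
#' prescribed power-law slope across the fractal regime.
#'
#' @param realization A `cspws_realization`.
#' @param r_max_nm Largest separation to report.
#' @param n_bins Number of radial bins.
#' @return A data frame with columns `r_nm` (bin centre) and `acf`.
#' @export
empirical_radial_acf <- function(realization, r_max_nm = 400, n_bins = 48) {
  g <- realization$grid
  ## subtract the known crowding mean, not the sample mean: removing the
  ## sample mean deletes the box's zero-frequency mode and biases the
  ## estimated long-range correlations downward
  x <- realization$density - realization$mean_crowding_g_ml
  n <- length(x)
  ft <- stats::fft(x)
  cc <- Re(stats::fft(ft * Conj(ft), inverse = TRUE)) / n / n
  dy <- .min_image_dist(g$ny, g$voxel_nm)
  dx <- .min_image_dist(g$nx, g$voxel_nm)
  dz <- .min_image_dist(g$nz, g$voxel_nm)
  rr <- sqrt(outer(outer(dy^2, dx^2, "+"), dz^2, "+"))
  keep <- rr <= r_max_nm
  bins <- cut(rr[keep], breaks = seq(0, r_max_nm, length.out = n_bins + 1),
              include.lowest = TRUE)
  means <- tapply(cc[keep], bins, mean)
  centres <- (seq(0, r_max_nm, length.out = n_bins + 1)[-1] +
              seq(0, r_max_nm, length.out = n_bins + 1)[-(n_bins + 1)]) / 2
  data.frame(r_nm = centres[!is.na(means)], acf = as.numeric(means[!is.na(means)]))
}

.min_image_dist <- function(n, voxel_nm) {
  m <- 0:(n - 1)
  pmin(m, n - m) * voxel_nm
}

#' @export
print.cspws_realization <- function(x, ...) {
  g <- x$grid
  cat(sprintf("chromatin realization: %d x %d x %d @ %g nm, d_b = %.3g, seed %d\n",
              g$ny, g$nx, g$nz, g$voxel_nm, x$model$d_b, x$seed))
  invisible(x)
}
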