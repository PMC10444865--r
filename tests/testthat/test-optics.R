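test_that("density-to-RI follows the linear mixing relation", {
  inst <- make_default_instrument()
  g <- grid_spec(4, 4, 8, 10)
  mk <- function(rho) {
    rl <- list(density = array(rho, c(4, 4, 8)), grid = g, model = acf_model(2),
               seed = 0, mean_crowding_g_ml = 0)
    class(rl) <- "cspws_realization"
    rl
  }
  expect_true(all(density_to_ri(mk(0), inst)$values == inst$n_media))
  expect_equal(density_to_ri(mk(1), inst)$values[1], 1.364 + 0.18, tolerance = 1e-12)
  ## affinity: n(a r1 + b r2) - n_media = a (n(r1) - n_media) + b (n(r2) - n_media)
  r1 <- array(runif(128), c(4, 4, 8))
  r2 <- array(runif(128), c(4, 4, 8))
  lhs <- density_to_ri(mk(2 * r1 + 3 * r2), inst)$values - inst$n_media
  rhs <- 2 * (density_to_ri(mk(r1), inst)$values - inst$n_media) +
    3 * (density_to_ri(mk(r2), inst)$values - inst$n_media)
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("a homogeneous cell produces a wavelength-flat spectrum and zero Sigma", {
  inst <- make_default_instrument()
  g <- grid_spec(6, 6, 400, 10)
  ri <- ri_field(array(1.4, c(6, 6, 400)), g)
  raw <- simulate_interference_cube(ri, inst)
  expect_equal(max(apply(raw$values, c(1, 2), function(s) diff(range(s)))), 0)
  norm <- reference_normalize(raw, simulate_reference_cube(inst, 6, 6))
  sg <- compute_sigma_image(norm)
  expect_true(all(sg$sigma == 0))
})

test_that("a thin layer interferes at the two-wave beat frequency pi/z", {
  inst <- make_default_instrument()
  nz <- 512L
  g <- grid_spec(4, 4, nz, 10)
  vals <- array(inst$n_media, c(4, 4, nz))
  z_layer <- 2870  # nm, near the window centre
  vals[, , z_layer / 10 + 1] <- inst$n_media + 0.05
  cube <- simulate_interference_cube(ri_field(vals, g), inst)
  spec <- cube$values[1, 1, ]
  di <- spec - mean(spec)
  n_cell <- mean(vals)
  k <- 2 * pi * n_cell / cube$wavelengths_nm
  ## oscillation sits at frequency 2 z in k: the matched two-wave basis
  ## explains the spectrum; a 15% detuned basis does not
  fit <- lm(di ~ sin(2 * k * z_layer) + cos(2 * k * z_layer))
  r2 <- summary(fit)$r.squared
  fit_off <- lm(di ~ sin(2 * k * z_layer * 1.15) + cos(2 * k * z_layer * 1.15))
  expect_gt(r2, 0.98)
  expect_lt(summary(fit_off)$r.squared, 0.5)
})

test_that("spectral fluctuation amplitude is first-order linear in density", {
  inst <- make_default_instrument()
  g <- test_grid_small()
  tmpl <- acf_model(2.3, amplitude = 1e-5)
  m2 <- acf_model(2.3, amplitude = 4e-5)   # doubled fluctuation amplitude
  s1 <- compute_sigma_image(simulate_cell_cube(tmpl, g, inst, seed = 21))
  s2 <- compute_sigma_image(simulate_cell_cube(m2, g, inst, seed = 21))
  ratio <- mean(s2$sigma) / mean(s1$sigma)
  expect_equal(ratio, 2, tolerance = 0.02)
})

test_that("reference normalization is elementwise and unit-stable", {
  lam <- c(500, 510, 520)
  raw <- spectral_cube(array(rep(c(1.8, 2.0, 2.2), each = 4), c(2, 2, 3)), lam)
  ref_flat <- spectral_cube(array(2, c(2, 2, 3)), lam)
  nrm <- reference_normalize(raw, ref_flat)
  expect_equal(nrm$values[1, 1, ], c(0.9, 1.0, 1.1))
  expect_equal(reference_normalize(raw, raw)$values, array(1, c(2, 2, 3)))
  ones <- spectral_cube(array(1, c(2, 2, 3)), lam)
  expect_equal(reference_normalize(nrm, ones)$values, nrm$values)
  ref_bad <- spectral_cube(array(c(0, rep(1, 11)), c(2, 2, 3)), lam)
  expect_error(reference_normalize(raw, ref_bad), "positive")
  ref_wl <- spectral_cube(array(2, c(2, 2, 3)), lam + 1)
  expect_error(reference_normalize(raw, ref_wl), "wavelength")
})

test_that("Sigma is the n-1 spectral standard deviation and respects the mask", {
  lam <- c(500, 510, 520)
  cube <- spectral_cube(array(rep(c(0.9, 1.0, 1.1), each = 4), c(2, 2, 3)), lam)
  mask <- matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2)
  sg <- compute_sigma_image(cube, mask)
  expect_equal(sg$sigma[1, 1], 0.1, tolerance = 1e-12)
  expect_true(is.nan(sg$sigma[2, 2]))
  ## permutation invariance over the wavelength axis
  rev_cube <- spectral_cube(cube$values[, , 3:1], lam)
  expect_equal(compute_sigma_image(rev_cube, mask)$sigma[1, 1], 0.1)
  ## constant spectrum
  flat <- spectral_cube(array(1, c(2, 2, 3)), lam)
  expect_true(all(compute_sigma_image(flat)$sigma == 0))
  two <- spectral_cube(array(1, c(2, 2, 2)), lam[1:2])
  expect_error(compute_sigma_image(two), "3 wavelengths")
})

test_that("fused cell simulation agrees with the composed route", {
  inst <- make_default_instrument()
  g <- test_grid_small()
  m <- anchored_acf_model(test_template(), 2.1)
  fused <- simulate_cell_cube(m, g, inst, seed = 31)
  rl <- sample_chromatin_density(m, g, seed = 31)
  composed <- reference_normalize(
    simulate_interference_cube(density_to_ri(rl, inst), inst),
    simulate_reference_cube(inst, g$ny, g$nx))
  ## identical noise stream; the only difference is that the composed route
  ## estimates the mean cell RI from the realization itself
  s_f <- compute_sigma_image(fused)$sigma
  s_c <- compute_sigma_image(composed)$sigma
  expect_gt(cor(as.numeric(s_f), as.numeric(s_c)), 0.999)
  expect_lt(abs(mean(s_f) / mean(s_c) - 1), 0.02)
})
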