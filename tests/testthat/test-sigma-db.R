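test_that("smoothing kernel converts the coherence FWHM lengths to sigmas", {
  inst <- make_default_instrument()
  k <- smoothing_kernel(inst)
  f <- 2 * sqrt(2 * log(2))
  expect_equal(k$transverse_sigma_nm, 458 / f, tolerance = 1e-12)
  expect_equal(k$axial_sigma_nm, 2874 / f, tolerance = 1e-12)
  ## widths scale linearly with the configured lengths
  inst2 <- instrument_config(transverse_coherence_nm = 916,
                             depth_of_field_nm = 5748)
  k2 <- smoothing_kernel(inst2)
  expect_equal(k2$transverse_sigma_nm / k$transverse_sigma_nm, 2)
  expect_equal(k2$axial_sigma_nm / k$axial_sigma_nm, 2)
})

test_that("forward map scales as the square root of the amplitude", {
  inst <- test_instrument()
  m1 <- acf_model(2.3, amplitude = 4e-4)
  m2 <- acf_model(2.3, amplitude = 8e-4)
  expect_equal(sigma_from_db(acf_model(2.3, amplitude = 0), instrument = inst), 0)
  s1 <- sigma_from_db(m1, instrument = inst)
  s2 <- sigma_from_db(m2, instrument = inst)
  expect_equal(s2 / s1, sqrt(2), tolerance = 1e-9)
})

test_that("lookup table is strictly monotone with physical endpoints", {
  map <- test_map_cont()
  expect_equal(map$d_b_grid[1], 5 / 3)
  expect_equal(map$d_b_grid[length(map$d_b_grid)], 3)
  dd <- diff(map$sigma_grid)
  expect_true(all(dd > 0) || all(dd < 0))
  expect_true(map$direction %in% c("increasing", "decreasing"))
  ## doubling the template amplitude scales sigma by sqrt(2), d_b unchanged
  tmpl2 <- acf_model(2.2, amplitude = 2 * test_template()$amplitude)
  map2 <- build_sigma_db_lookup(tmpl2, instrument = test_instrument(),
                                grid_size = 65)
  expect_equal(map2$d_b_grid, map$d_b_grid)
  expect_equal(map2$sigma_grid / map$sigma_grid,
               rep(sqrt(2), length(map$sigma_grid)), tolerance = 1e-9)
})

test_that("inversion is exact on table nodes and clamps out-of-range Sigma", {
  map <- test_map_cont()
  inv <- invert_sigma_to_db(map$sigma_grid, map)
  expect_equal(inv$d_b, map$d_b_grid, tolerance = 1e-9)
  expect_false(any(inv$clamped))
  ## Sigma below the table range clamps (flagged) to the low-Sigma endpoint
  low_end <- map$d_b_grid[which.min(map$sigma_grid)]
  hi_end <- map$d_b_grid[which.max(map$sigma_grid)]
  out <- invert_sigma_to_db(c(0, 2 * max(map$sigma_grid)), map)
  expect_equal(out$d_b, c(low_end, hi_end))
  expect_true(all(out$clamped))
})

test_that("round trip through the lookup is tight at interior d_b", {
  map <- test_map_cont()
  inst <- test_instrument()
  s <- sigma_from_db(anchored_acf_model(test_template(), 2.4),
                     instrument = inst)
  inv <- invert_sigma_to_db(s, map)
  expect_false(inv$clamped)
  expect_lt(abs(inv$d_b - 2.4), 1e-3)
})

test_that("Sigma image converts pointwise to a D image with clamp accounting", {
  map <- test_map_cont()
  ## uniform Sigma -> uniform D
  mask <- matrix(TRUE, 8, 8)
  s_mid <- map$sigma_grid[33]
  sg <- compute_sigma_image(spectral_cube(array(1, c(8, 8, 3)), 1:3), mask)
  sg$sigma[] <- s_mid
  dimg <- sigma_image_to_d_image(sg, map)
  expect_equal(length(unique(dimg$d[mask])), 1)
  expect_equal(unique(dimg$d[mask]), map$packing_d_grid[33], tolerance = 1e-9)
  expect_equal(dimg$clamped_fraction, 0)
  ## all-zero Sigma -> fully clamped
  sg$sigma[] <- 0
  expect_equal(sigma_image_to_d_image(sg, map)$clamped_fraction, 1)
  ## D stays inside the physical range whatever Sigma does
  set.seed(2)
  sg$sigma[] <- runif(64, 0, 2 * max(map$sigma_grid))
  d2 <- sigma_image_to_d_image(sg, map)
  expect_true(all(d2$d[mask] >= 5 / 3 - 1e-9 & d2$d[mask] <= 3 + 1e-9))
})

test_that("variance smoothing preserves a uniform Sigma image", {
  map <- test_map_cont()
  mask <- matrix(TRUE, 12, 12)
  sg <- list(sigma = matrix(map$sigma_grid[20], 12, 12), mask = mask)
  class(sg) <- "cspws_sigma_image"
  d0 <- sigma_image_to_d_image(sg, map, smooth_radius_px = 0)
  d3 <- sigma_image_to_d_image(sg, map, smooth_radius_px = 3)
  expect_equal(d0$d, d3$d, tolerance = 1e-9)
})

test_that("lookup tables serialize to JSON and restore losslessly", {
  td <- withr::local_tempdir()
  map <- test_map_cont()
  p <- file.path(td, "map.json")
  write_sigma_db_map(map, p)
  back <- read_sigma_db_map(p)
  expect_equal(back$d_b_grid, map$d_b_grid)
  expect_equal(back$sigma_grid, map$sigma_grid)
  expect_identical(back$direction, map$direction)
  expect_equal(back$provenance$anchor_nm, map$provenance$anchor_nm)
  ## a restored map inverts identically
  s <- map$sigma_grid[c(5, 30, 60)]
  expect_equal(invert_sigma_to_db(s, back)$d_b, invert_sigma_to_db(s, map)$d_b)
})
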