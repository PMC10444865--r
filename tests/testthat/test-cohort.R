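test_that("cohort generation produces the configured structure, deterministically", {
  sp <- cohort_spec(n_case = 42, n_control = 40, cells_per_patient = 30,
                    seed = 5)
  man <- generate_cohort(sp)
  expect_equal(nrow(man$patients), 82)
  expect_equal(nrow(man$cells), 82 * 30)
  expect_false(any(duplicated(man$patients$patient_id)))
  expect_equal(sum(man$patients$group == "case"), 42)
  man2 <- generate_cohort(sp)
  expect_identical(man$patients, man2$patients)
  expect_identical(man$cells, man2$cells)
  ## rendered images are reproducible too
  r1 <- render_d_image(man$cells$cell_mean_d[1], sp, man$cells$render_seed[1])
  r2 <- render_d_image(man$cells$cell_mean_d[1], sp, man$cells$render_seed[1])
  expect_identical(r1$d_image$d, r2$d_image$d)
})

test_that("all generated D values respect the physical range", {
  sp <- cohort_spec(n_case = 30, n_control = 30, cells_per_patient = 10,
                    effect_delta_d = 0.8, between_patient_sd = 0.3,
                    between_cell_sd = 0.4, seed = 8)
  man <- generate_cohort(sp)
  expect_true(all(man$patients$true_mean_d >= 5 / 3 & man$patients$true_mean_d <= 3))
  expect_true(all(man$cells$cell_mean_d >= 5 / 3 & man$cells$cell_mean_d <= 3))
  r <- render_d_image(max(man$cells$cell_mean_d), sp, 1)
  expect_true(all(r$d_image$d[r$mask] >= 5 / 3 & r$d_image$d[r$mask] <= 3))
})

test_that("a null cohort has exchangeable groups and degenerate noise collapses", {
  sp0 <- cohort_spec(n_case = 200, n_control = 200, cells_per_patient = 2,
                     effect_delta_d = 0, age_slope_per_year = 0, seed = 13)
  man <- generate_cohort(sp0)
  ks <- ks.test(man$patients$true_mean_d[man$patients$group == "case"],
                man$patients$true_mean_d[man$patients$group == "control"])
  expect_gt(ks$p.value, 0.005)
  spd <- cohort_spec(n_case = 5, n_control = 5, cells_per_patient = 2,
                     between_patient_sd = 0, age_slope_per_year = 0, seed = 2)
  mand <- generate_cohort(spd)
  ctrl <- mand$patients$true_mean_d[mand$patients$group == "control"]
  expect_equal(diff(range(ctrl)), 0)
})

test_that("zero-effect cohorts keep the two-sample type-I error nominal", {
  rejections <- 0
  for (rep in 1:100) {
    sp <- cohort_spec(n_case = 40, n_control = 40, cells_per_patient = 2,
                      effect_delta_d = 0, age_slope_per_year = 0,
                      seed = 4000 + rep)
    man <- generate_cohort(sp)
    p <- t.test(true_mean_d ~ group, data = man$patients)$p.value
    if (p < 0.01) rejections <- rejections + 1
  }
  expect_lte(rejections, 5)  # >= 95% non-significant at alpha = 0.01
})

test_that("the injected control age slope is recoverable by regression", {
  sp <- cohort_spec(n_case = 2, n_control = 500, cells_per_patient = 2,
                    seed = 77)
  man <- generate_cohort(sp)
  ctrl <- man$patients[man$patients$group == "control", ]
  fit <- lm(true_mean_d ~ age, data = ctrl)
  ci <- confint(fit)["age", ]
  expect_gt(-0.006, ci[1])
  expect_lt(-0.006, ci[2])
})

test_that("demographic marginals match the spec within Monte-Carlo error", {
  sp <- cohort_spec(n_case = 250, n_control = 250, cells_per_patient = 2,
                    seed = 31)
  man <- generate_cohort(sp)
  cases <- man$patients[man$patients$group == "case", ]
  ctrls <- man$patients[man$patients$group == "control", ]
  expect_gt(prop.test(sum(cases$gender == "female"), nrow(cases),
                      p = 0.56)$p.value, 0.01)
  expect_gt(prop.test(sum(ctrls$race == "caucasian"), nrow(ctrls),
                      p = 0.80)$p.value, 0.01)
  expect_lt(abs(mean(ctrls$age) - 59), 3 * 11 / sqrt(250) + 1)
  expect_lt(abs(mean(cases$age) - 67), 3 * 12 / sqrt(250) + 1)
})

test_that("rendering reproduces the requested in-mask mean and geometry", {
  sp <- test_cohort_spec_small()
  ## no texture -> exactly constant in-mask
  sp0 <- test_cohort_spec_small(texture_sd = 0, domain_contrast_per_d = 0)
  r0 <- render_d_image(2.3, sp0, seed = 3)
  expect_equal(unique(r0$d_image$d[r0$mask]), 2.3, tolerance = 1e-12)
  ## Monte-Carlo mean over 100 cells
  means <- sapply(1:100, function(s) {
    r <- render_d_image(2.2, sp, seed = 9000 + s)
    mean(r$d_image$d[r$mask])
  })
  expect_lt(abs(mean(means) - 2.2), 0.01)
  ## mask area within the configured nucleus-geometry bounds
  areas <- sapply(1:20, function(s) sum(render_d_image(2.2, sp, s)$mask))
  a_min <- pi * sp$nucleus_semiaxis_px[1]^2 * sp$nucleus_axis_ratio[1]
  a_max <- pi * sp$nucleus_semiaxis_px[2]^2 * sp$nucleus_axis_ratio[2]
  expect_true(all(areas >= 0.85 * a_min & areas <= 1.15 * a_max))
  ## background is NaN
  r <- render_d_image(2.2, sp, 1)
  expect_true(all(is.nan(r$d_image$d[!r$mask])))
})

test_that("domain radii are log-normal around the configured 80 nm mean", {
  sp <- cohort_spec()
  set.seed(123)
  rr <- sample_domain_radii(10000, sp)
  expect_true(all(rr > 0))
  se <- sp$domain_radius_sd_nm / sqrt(10000)
  expect_lt(abs(mean(rr) - sp$domain_radius_mean_nm), 4 * se)
  expect_lt(abs(sd(rr) - sp$domain_radius_sd_nm), 0.1 * sp$domain_radius_sd_nm)
})

test_that("a small spectral cohort bridges to the instrument model", {
  inst <- test_instrument()
  g <- test_grid_small()
  sp <- cohort_spec(n_case = 1, n_control = 1, cells_per_patient = 3,
                    seed = 17)
  sc <- generate_spectral_cohort(sp, inst, g, model_template = test_template())
  expect_length(sc$cubes, 6)
  expect_s3_class(sc$cubes[[1]], "cspws_cube")
  expect_equal(dim(sc$cubes[[1]]$values), c(g$ny, g$nx, 84))
  ## amplitude-zero chromatin -> zero Sigma -> fully clamped D images
  m0 <- acf_model(2.2, amplitude = 0)
  cube0 <- simulate_cell_cube(m0, g, inst, seed = 1)
  sg0 <- compute_sigma_image(cube0)
  expect_equal(sigma_image_to_d_image(sg0, test_map_cont())$clamped_fraction, 1)
})

test_that("recovered in-mask mean D tracks true cell D across a spectral cohort", {
  inst <- test_instrument()
  g <- grid_spec(160, 160, 512, 10)
  map <- build_sigma_db_lookup(test_template(), instrument = inst,
                               geometry = g, grid_size = 65)
  ## 12 cells spanning the physiological D range
  sp <- cohort_spec(n_case = 2, n_control = 2, cells_per_patient = 3,
                    seed = 29)
  man <- generate_cohort(sp)
  man$cells$cell_mean_d <- seq(1.8, 2.7, length.out = nrow(man$cells))
  sc <- generate_spectral_cohort(sp, inst, g, model_template = test_template(),
                                 manifest = man)
  rec <- sapply(seq_along(sc$cubes), function(j) {
    sg <- compute_sigma_image(sc$cubes[[j]])
    dimg <- sigma_image_to_d_image(sg, map, smooth_radius_px = 80)
    mean(dimg$d[dimg$mask])
  })
  truth <- sc$manifest$cells$cell_mean_d
  expect_gt(cor(rec, truth, method = "spearman"), 0.9)
})
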