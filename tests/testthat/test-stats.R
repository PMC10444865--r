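## Cohort whose per-cell D values are fixed by construction.
fixed_cohort <- function(ctrl_d, case_d, n_ctrl = 5, n_case = 5, cells = 4) {
  sp <- cohort_spec(n_case = n_case, n_control = n_ctrl,
                    cells_per_patient = cells, seed = 1)
  man <- generate_cohort(sp)
  man$cells$cell_mean_d <- ifelse(
    man$cells$patient_id %in% man$patients$patient_id[man$patients$group == "case"],
    case_d, ctrl_d)
  man
}

test_that("patient averaging and control normalization behave as defined", {
  man <- fixed_cohort(2.0, 2.0)
  pts <- patient_mean_d(man)
  expect_true(all(pts$normalized_d == 1))
  man2 <- fixed_cohort(2.0, 2.2)
  pts2 <- patient_mean_d(man2)
  expect_equal(unique(pts2$normalized_d[pts2$group == "case"]), 1.1)
  ## normalization fixed point
  sp <- cohort_spec(n_case = 12, n_control = 12, cells_per_patient = 5, seed = 6)
  pts3 <- patient_mean_d(generate_cohort(sp))
  expect_lt(abs(mean(pts3$normalized_d[pts3$group == "control"]) - 1), 1e-12)
  ## permuting cells leaves the result unchanged
  man3 <- generate_cohort(sp)
  man3$cells <- man3$cells[sample.int(nrow(man3$cells)), ]
  expect_equal(patient_mean_d(man3)$mean_nuclear_d, pts3$mean_nuclear_d)
})

test_that("patients without usable cells are dropped with a warning", {
  man <- fixed_cohort(2.0, 2.2)
  drop_id <- man$patients$patient_id[1]
  qc <- data.frame(cell_id = man$cells$cell_id,
                   keep = man$cells$patient_id != drop_id)
  expect_warning(pts <- patient_mean_d(man, qc = qc), "zero kept cells")
  expect_false(drop_id %in% pts$patient_id)
})

test_that("ANCOVA recovers an injected age slope and rejects collinearity", {
  sp <- cohort_spec(n_case = 250, n_control = 250, cells_per_patient = 2,
                    seed = 41)
  man <- generate_cohort(sp)
  pts <- patient_mean_d(man)
  an <- ancova_d(pts)
  expect_true(all(c("group", "age", "pack_years", "gender", "race") %in%
                  an$table$term))
  expect_true(all(an$table$p >= 0 & an$table$p <= 1))
  ## the age slope on normalized D corresponds to slope / control mean D
  ctrl_mean <- mean(pts$mean_nuclear_d[pts$group == "control"])
  slope_age <- an$table$slope[an$table$term == "age"]
  se_age <- sqrt(diag(vcov(an$model)))["age"]
  expect_lt(abs(slope_age - (-0.006 / ctrl_mean)), 3 * se_age)
  ## duplicated covariate -> rank deficiency error naming the term
  pts$age_copy <- pts$age
  expect_error(ancova_d(pts, c("group", "age", "age_copy")), "collinear")
  pts$const <- 1
  expect_error(ancova_d(pts, c("group", "const")), "constant")
  expect_error(ancova_d(pts[1:8, ]), "10 patients")
})

test_that("subgroup regression is exact on noiseless data", {
  pts <- data.frame(normalized_d = 1 - 0.006 * ((40:80) - 60), age = 40:80,
                    group = "control")
  ## noiseless fits trigger lm's perfect-fit warning; the slopes are the point
  fit <- suppressWarnings(subgroup_regression(pts, "age"))
  expect_equal(fit$slope, -0.006, tolerance = 1e-12)
  const <- data.frame(normalized_d = rep(1, 10), age = 1:10, group = "control")
  expect_equal(suppressWarnings(subgroup_regression(const, "age"))$slope, 0,
               tolerance = 1e-12)
  expect_error(subgroup_regression(pts[1:2, ], "age"), "small")
})

test_that("age adjustment residualizes the control age trend", {
  sp <- cohort_spec(n_case = 60, n_control = 60, cells_per_patient = 3,
                    seed = 23)
  pts <- patient_mean_d(generate_cohort(sp))
  adj0 <- age_adjust(pts, control_slope = 0)
  expect_equal(adj0$adjusted_d, pts$normalized_d)
  adj <- age_adjust(pts)
  resid_slope <- subgroup_regression(adj, "age", adj$group == "control",
                                     response = "adjusted_d")$slope
  expect_lt(abs(resid_slope), 1e-10)
  pts$age[3] <- NA
  expect_warning(adj2 <- age_adjust(pts), "lack age")
  expect_true(is.na(adj2$adjusted_d[3]))
})

test_that("age adjustment restores the AUC lost to the age-group confound", {
  ## cases are older and D falls with age, so the raw average-D AUC sits
  ## below the unconfounded value; adjustment recovers most of the gap.
  ## Normal-theory oracle for the expected AUCs under the generator model:
  sp <- cohort_spec(seed = 1)
  sd_tot <- sqrt(sp$between_patient_sd^2 +
                 sp$between_cell_sd^2 / sp$cells_per_patient)
  delta_age <- -sp$age_slope_per_year *
    (sp$age_mean_case - sp$age_mean_control)
  auc_adj_pred <- pnorm(sp$effect_delta_d / (sd_tot * sqrt(2)))
  auc_raw_pred <- pnorm((sp$effect_delta_d - delta_age) / (sd_tot * sqrt(2)))
  set.seed(77)
  diffs <- replicate(15, {
    spi <- cohort_spec(seed = sample.int(1e6, 1))
    pts <- patient_mean_d(generate_cohort(spi))
    adj <- age_adjust(pts)
    c(raw = average_d_auc(pts)$auc,
      adj = average_d_auc(adj, "adjusted_d")$auc)
  })
  expect_lt(abs(mean(diffs["raw", ]) - auc_raw_pred), 0.05)
  expect_lt(abs(mean(diffs["adj", ]) - auc_adj_pred), 0.05)
  expect_gt(mean(diffs["adj", ] - diffs["raw", ]), 0)
})

test_that("average-D AUC matches the shared rank-AUC implementation exactly", {
  sp <- cohort_spec(n_case = 25, n_control = 25, cells_per_patient = 3,
                    seed = 71)
  pts <- patient_mean_d(generate_cohort(sp))
  got <- average_d_auc(pts)
  expect_identical(got$auc,
                   roc_auc(pts$normalized_d,
                           factor(pts$group, levels = c("control", "case"))))
  ## degenerate cohorts
  man0 <- fixed_cohort(2.0, 2.0, 10, 10)
  expect_equal(average_d_auc(patient_mean_d(man0))$auc, 0.5)
  man1 <- fixed_cohort(2.0, 2.4, 10, 10)
  expect_equal(average_d_auc(patient_mean_d(man1))$auc, 1)
})

test_that("pack-year strata use the exact rank-sum null at small n", {
  ## complete separation at the Fig.-5-style stratum sizes (7 vs 14)
  pts <- data.frame(
    group = c(rep("control", 7), rep("case", 14), rep("control", 3),
              rep("case", 3)),
    normalized_d = c(seq(0.90, 0.96, length.out = 7),
                     seq(1.05, 1.18, length.out = 14),
                     1.0, 1.1, 0.95, 1.02, 1.2, 0.9),
    pack_years = c(rep(5, 21), rep(30, 6)))
  res <- packyear_subgroup_test(pts, cut = 20)
  low <- res[res$stratum == "low_risk", ]
  expect_equal(low$n_case, 14)
  expect_equal(low$n_control, 7)
  expect_equal(low$p, 2 / choose(21, 7), tolerance = 1e-12)
  ## null calibration: rejection rate at 5% stays nominal
  set.seed(91)
  ps <- replicate(120, {
    d <- data.frame(group = rep(c("control", "case"), each = 20),
                    normalized_d = rnorm(40, 1, 0.05),
                    pack_years = runif(40, 0, 40))
    packyear_subgroup_test(d)$p
  })
  rate <- mean(ps < 0.05, na.rm = TRUE)
  expect_gt(rate, 0.001)
  expect_lt(rate, 0.12)
  ## an empty stratum reports NA rather than failing
  pts2 <- pts[pts$pack_years < 20, ]
  res2 <- packyear_subgroup_test(pts2)
  expect_true(is.na(res2$p[res2$stratum == "high_risk"]))
})

test_that("the demographic table summarizes both groups with p-values", {
  sp <- cohort_spec(n_case = 60, n_control = 60, cells_per_patient = 2,
                    seed = 19)
  man <- generate_cohort(sp)
  tab <- demographic_table(man$patients)
  expect_equal(tab$factor,
               c("Age", "Pack-years", "Gender (% female)",
                 "Race (% caucasian)"))
  expect_true(all(tab$p >= 0 & tab$p <= 1))
  ## the printed control age summary matches the sample moments
  ctrl <- man$patients[man$patients$group == "control", ]
  expect_identical(tab$control[1],
                   sprintf("%.0f +/- %.0f", mean(ctrl$age), sd(ctrl$age)))
})
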