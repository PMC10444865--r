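#' Per-patient average nuclear D, normalized by the control population
#'
#' Computes the unweighted mean of each patient's per-cell mean D over all
#' kept cells and divides by the control-group mean. When the cohort
#' spans several sites, normalization is per site, so the control mean of
#' `normalized_d` is 1 within every site. Patients with no usable cells
#' are dropped with a warning.
#'
#' @param manifest A `cspws_manifest`.
#' @param cell_values Optional named numeric vector (names = cell ids)
#'   replacing the manifest's `cell_mean_d`, e.g. in-mask means measured
#'   from reconstructed D images.
#' @param qc Optional QC report from [qc_report()]; cells with
#'   `keep == FALSE` are excluded.
#' @return Data frame with one row per patient: covariates, `n_cells`,
#'   `mean_nuclear_d`, `normalized_d`.
#' @export
patient_mean_d <- function(manifest, cell_values = NULL, qc = NULL) {
  cells <- manifest$cells
  vals <- cells$cell_mean_d
  if (!is.null(cell_values)) {
    vals <- unname(cell_values[cells$cell_id])
  }
  keep <- rep(TRUE, nrow(cells))
  if (!is.null(qc)) {
    keep <- cells$cell_id %in% qc$cell_id[qc$keep]
  }
  keep <- keep & is.finite(vals)
  agg <- tapply(vals[keep], cells$patient_id[keep], mean)
  n_cells <- tapply(vals[keep], cells$patient_id[keep], length)
  pts <- manifest$patients
  missing <- setdiff(pts$patient_id, names(agg))
  if (length(missing) > 0) {
    warning("excluding patients with zero kept cells: ",
            paste(missing, collapse = ", "))
    pts <- pts[!pts$patient_id %in% missing, , drop = FALSE]
  }
  pts$mean_nuclear_d <- as.numeric(agg[pts$patient_id])
  pts$n_cells <- as.integer(n_cells[pts$patient_id])
  pts$normalized_d <- NA_real_
  for (s in unique(pts$site)) {
    in_site <- pts$site == s
    ctrl_mean <- mean(pts$mean_nuclear_d[in_site & pts$group == "control"])
    pts$normalized_d[in_site] <- pts$mean_nuclear_d[in_site] / ctrl_mean
  }
  pts
}

#' ANCOVA of average D on group and demographic covariates
#'
#' Linear model of normalized D on group plus covariates with type-II F
#' tests per term. Reports the fitted slope for numeric covariates and
#' the second-level contrast for two-level factors.
#'
#' @param patients Data frame from [patient_mean_d()].
#' @param covariates Character vector of model terms.
#' @param response Response column name.
#' @return A `cspws_ancova`: list with `table` (term, slope, F, p),
#'   `formula`, and the fitted `model`.
#' @export
ancova_d <- function(patients,
                     covariates = c("group", "age", "pack_years", "gender",
                                    "race"),
                     response = "normalized_d") {
  if (nrow(patients) < 10) stop("ANCOVA requires at least 10 patients")
  for (cv in covariates) {
    v <- patients[[cv]]
    if (is.null(v)) stop("covariate not found: ", cv)
    if (length(unique(v)) < 2) stop("constant covariate: ", cv)
  }
  dat <- patients[, c(response, covariates), drop = FALSE]
  for (cv in covariates) {
    if (is.character(dat[[cv]])) {
      if (setequal(unique(dat[[cv]]), c("control", "case"))) {
        dat[[cv]] <- factor(dat[[cv]], levels = c("control", "case"))
      } else {
        dat[[cv]] <- factor(dat[[cv]])
      }
    }
  }
  fml <- stats::as.formula(paste(response, "~",
                                 paste(covariates, collapse = " + ")))
  fit <- stats::lm(fml, data = dat)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient ANCOVA design; collinear terms: ",
         paste(bad, collapse = ", "))
  }
  an <- car::Anova(fit, type = 2)
  cf <- stats::coef(fit)
  tab <- do.call(rbind, lapply(covariates, function(term) {
    slope <- NA_real_
    hit <- grep(paste0("^", term), names(cf), value = TRUE)
    if (length(hit) == 1) slope <- unname(cf[hit])
    data.frame(term = term, slope = slope,
               F = an[term, "F value"], p = an[term, "Pr(>F)"],
               stringsAsFactors = FALSE)
  }))
  obj <- list(table = tab, formula = deparse(fml), model = fit)
  class(obj) <- "cspws_ancova"
  obj
}

#' @export
print.cspws_ancova <- function(x, ...) {
  cat("ANCOVA (type-II F tests):", x$formula, "\n")
  print(transform(x$table, p = signif(p, 3), F = signif(F, 4),
                  slope = signif(slope, 3)), row.names = FALSE)
  invisible(x)
}

#' Subgroup linear regression of normalized D on a covariate
#'
#' Ordinary least squares within a patient subgroup (e.g. controls only),
#' as used to quantify demographic trends of average D.
#'
#' @param patients Data frame from [patient_mean_d()].
#' @param covariate Covariate column name (numeric).
#' @param subgroup Optional logical vector selecting the subgroup.
#' @param response Response column name.
#' @return List with `slope`, `ci` (95%), `n`, `p`, `intercept`.
#' @export
subgroup_regression <- function(patients, covariate, subgroup = NULL,
                                response = "normalized_d") {
  dat <- if (is.null(subgroup)) patients else patients[subgroup, , drop = FALSE]
  if (nrow(dat) < 3) stop("subgroup too small (need >= 3 patients)")
  fml <- stats::as.formula(paste(response, "~", covariate))
  fit <- stats::lm(fml, data = dat)
  ci <- stats::confint(fit)[2, ]
  sm <- summary(fit)$coefficients
  list(slope = unname(stats::coef(fit)[2]),
       ci = unname(ci), n = nrow(dat),
       p = if (nrow(sm) > 1) sm[2, 4] else NA_real_,
       intercept = unname(stats::coef(fit)[1]))
}

#' Age adjustment of normalized D
#'
#' Subtracts the control-population age trend:
#' `adjusted_d = normalized_d - slope * (age - control mean age)`.
#' Patients with missing age keep `adjusted_d = NA` and are flagged.
#'
#' @param patients Data frame from [patient_mean_d()].
#' @param control_slope Age slope per year; when `NULL` it is estimated by
#'   [subgroup_regression()] on the controls.
#' @param response Column to adjust.
#' @return `patients` with columns `adjusted_d` and `age_missing`.
#' @export
age_adjust <- function(patients, control_slope = NULL,
                       response = "normalized_d") {
  if (is.null(control_slope)) {
    control_slope <- subgroup_regression(patients, "age",
                                         patients$group == "control",
                                         response)$slope
  }
  ctrl_age <- mean(patients$age[patients$group == "control"], na.rm = TRUE)
  patients$age_missing <- !is.finite(patients$age)
  patients$adjusted_d <- patients[[response]] -
    control_slope * (patients$age - ctrl_age)
  patients$adjusted_d[patients$age_missing] <- NA_real_
  if (any(patients$age_missing)) {
    warning(sum(patients$age_missing), " patient(s) lack age; not adjusted")
  }
  attr(patients, "control_slope") <- control_slope
  patients
}

#' ROC AUC of average nuclear D as a one-dimensional classifier
#'
#' @param patients Data frame from [patient_mean_d()] (optionally
#'   age-adjusted).
#' @param value Score column (`"normalized_d"` or `"adjusted_d"`).
#' @return List with `auc` and the ROC coordinates (`data.frame` with
#'   threshold, sensitivity, specificity).
#' @export
average_d_auc <- function(patients, value = "normalized_d") {
  sc <- patients[[value]]
  ok <- is.finite(sc)
  labels <- factor(patients$group[ok], levels = c("control", "case"))
  if (length(unique(labels)) < 2) stop("both groups must be present")
  sc <- sc[ok]
  auc <- roc_auc(sc, labels)
  cand <- c(-Inf, sort(unique(sc)))
  roc <- data.frame(
    threshold = cand,
    sensitivity = vapply(cand, function(t) mean(sc[labels == "case"] >= t),
                         numeric(1)),
    specificity = vapply(cand, function(t) mean(sc[labels == "control"] < t),
                         numeric(1)))
  list(auc = auc, roc = roc)
}

#' Case-control comparison within smoking-risk strata
#'
#' Stratifies patients at a pack-year cut (default 20, the LDCT
#' eligibility boundary), and runs a two-sided Wilcoxon rank-sum test of
#' normalized D between cases and controls within each stratum; the exact
#' null distribution is used whenever the smaller group has at most 10
#' patients and there are no ties. Empty strata are reported as not
#' computable rather than failing.
#'
#' @param patients Data frame from [patient_mean_d()].
#' @param cut Pack-year threshold.
#' @param value Response column.
#' @return Data frame with one row per stratum: counts, group medians and
#'   the rank-sum p value (`NA` when not computable).
#' @export
packyear_subgroup_test <- function(patients, cut = 20,
                                   value = "normalized_d") {
  strata <- ifelse(patients$pack_years < cut, "low_risk", "high_risk")
  out <- lapply(c("low_risk", "high_risk"), function(s) {
    dat <- patients[strata == s, , drop = FALSE]
    n_case <- sum(dat$group == "case")
    n_ctrl <- sum(dat$group == "control")
    p <- NA_real_
    if (n_case >= 1 && n_ctrl >= 1) {
      x <- dat[[value]][dat$group == "case"]
      y <- dat[[value]][dat$group == "control"]
      exact <- min(n_case, n_ctrl) <= 10 && !any(duplicated(c(x, y)))
      p <- stats::wilcox.test(x, y, alternative = "two.sided",
                              exact = exact)$p.value
    }
    data.frame(stratum = s, n_case = n_case, n_control = n_ctrl,
               median_case = stats::median(dat[[value]][dat$group == "case"]),
               median_control = stats::median(dat[[value]][dat$group == "control"]),
               p = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Demographic summary table of a cohort
#'
#' One row per demographic factor with the control and case summaries
#' (mean +/- SD for numeric factors, percentage for binary ones) and a
#' two-sided p-value for the group difference (Welch t-test or two-sample
#' proportion test).
#'
#' @param patients Data frame with `group`, `age`, `pack_years`, `gender`,
#'   `race` columns (e.g. from [patient_mean_d()] or a manifest's
#'   `patients`).
#' @return Data frame with columns `factor`, `control`, `case`, `p`.
#' @export
demographic_table <- function(patients) {
  ctrl <- patients[patients$group == "control", ]
  case <- patients[patients$group == "case", ]
  num_row <- function(name, col) {
    data.frame(
      factor = name,
      control = sprintf("%.0f +/- %.0f", mean(ctrl[[col]]), sd(ctrl[[col]])),
      case = sprintf("%.0f +/- %.0f", mean(case[[col]]), sd(case[[col]])),
      p = stats::t.test(patients[[col]] ~ patients$group)$p.value,
      stringsAsFactors = FALSE)
  }
  bin_row <- function(name, col, level) {
    x <- c(sum(ctrl[[col]] == level), sum(case[[col]] == level))
    n <- c(nrow(ctrl), nrow(case))
    p <- suppressWarnings(stats::prop.test(x, n)$p.value)
    data.frame(factor = name,
               control = sprintf("%.0f%%", 100 * x[1] / n[1]),
               case = sprintf("%.0f%%", 100 * x[2] / n[2]),
               p = p, stringsAsFactors = FALSE)
  }
  rbind(num_row("Age", "age"),
        num_row("Pack-years", "pack_years"),
        bin_row("Gender (% female)", "gender", "female"),
        bin_row("Race (% caucasian)", "race", "caucasian"))
}
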