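#' Pipeline run configuration
#'
#' Bundles the stage toggles, seeds and per-module configurations of a
#' full cohort run: generation, feature extraction, cross-validated
#' classification and cohort statistics. Every random stage has an
#' explicit seed, and a snapshot of the configuration is written into the
#' output directory so a run is reproducible from its artifacts alone.
#'
#' The default is a small demonstration profile (20 patients x 8 cells,
#' light backbone, 64 x 64 inputs) that runs end-to-end in a few minutes
#' on one CPU.
#'
#' @param out_dir Output directory.
#' @param cohort A `cspws_cohort_spec`.
#' @param backbone A `cspws_backbone`.
#' @param preproc A `cspws_preproc`.
#' @param cv A `cspws_cv_config`.
#' @param stages Character vector out of `"cohort"`, `"features"`,
#'   `"classify"`, `"stats"`.
#' @param write_images Write per-cell TIFF/PNG artifacts during cohort
#'   generation.
#' @return A `cspws_run_config`.
#' @export
run_config <- function(out_dir,
                       cohort = cohort_spec(n_case = 10, n_control = 10,
                                            cells_per_patient = 8,
                                            seed = 11),
                       backbone = backbone_spec(width_mult = 0.25, seed = 21),
                       preproc = preproc_config(target_size = c(64, 64)),
                       cv = cv_config(seed = 31),
                       stages = c("cohort", "features", "classify", "stats"),
                       write_images = FALSE) {
  obj <- list(out_dir = out_dir, cohort = cohort, backbone = backbone,
              preproc = preproc, cv = cv, stages = stages,
              write_images = write_images)
  class(obj) <- "cspws_run_config"
  obj
}

#' Validate a run configuration
#'
#' Returns every detected problem (missing stages, missing seeds,
#' inconsistent sizes) without side effects; an empty character vector
#' means the configuration is runnable. A negative case-control effect is
#' deliberately accepted: the direction of the D difference is data, not
#' an error.
#'
#' @param config A `cspws_run_config`.
#' @return Character vector of problems (empty if none).
#' @export
validate_config <- function(config) {
  problems <- character()
  known <- c("cohort", "features", "classify", "stats")
  bad <- setdiff(config$stages, known)
  if (length(bad) > 0) {
    problems <- c(problems, paste0("unknown stage(s): ",
                                   paste(bad, collapse = ", ")))
  }
  if (is.null(config$cohort$seed)) problems <- c(problems, "cohort seed missing")
  if (is.null(config$backbone$seed)) problems <- c(problems, "backbone seed missing")
  if (is.null(config$cv$seed)) problems <- c(problems, "cv seed missing")
  k2 <- 2 * config$backbone$k
  if (config$cv$n_keep >= k2) {
    problems <- c(problems,
                  sprintf("cv n_keep (%d) must be below the patient feature dimension (%d)",
                          config$cv$n_keep, k2))
  }
  n_min <- min(config$cohort$n_case, config$cohort$n_control)
  if ("classify" %in% config$stages && n_min < config$cv$n_folds) {
    problems <- c(problems,
                  sprintf("smallest class (%d) below n_folds (%d)",
                          n_min, config$cv$n_folds))
  }
  if (config$cohort$cells_per_patient < 2) {
    problems <- c(problems, "cells_per_patient must be >= 2")
  }
  problems
}

#' Run the csPWS analysis pipeline
#'
#' Executes the enabled stages in order (cohort generation, patient
#' feature extraction, repeated-CV classification, cohort statistics) and
#' writes each stage's artifact plus a run report with MD5 checksums of
#' everything produced. Reruns with an identical configuration produce
#' identical artifacts. Statistics are computed from average nuclear D
#' and do not require the classification stage.
#'
#' @param config A `cspws_run_config`.
#' @return The run report (named list), invisibly; also written as
#'   `run_report.json`.
#' @export
run_pipeline <- function(config) {
  problems <- validate_config(config)
  if (length(problems) > 0) {
    stop("invalid configuration:\n  - ", paste(problems, collapse = "\n  - "))
  }
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  artifacts <- character()
  manifest <- NULL
  if ("cohort" %in% config$stages) {
    manifest <- generate_cohort(config$cohort,
                                dir = file.path(out, "cohort"),
                                write_images = config$write_images)
    artifacts <- c(artifacts,
                   file.path(out, "cohort",
                             c("manifest.csv", "patients.csv",
                               "cohort_spec.json")))
  } else {
    manifest <- read_manifest(file.path(out, "cohort"))
  }
  feat <- NULL
  if ("features" %in% config$stages) {
    feat <- cohort_features(manifest, config$backbone, config$preproc)
    fpath <- file.path(out, "features.csv")
    utils::write.csv(data.frame(patient_id = feat$patient_ids,
                                group = as.character(feat$labels),
                                feat$features, check.names = FALSE),
                     fpath, row.names = FALSE)
    jsonlite::write_json(
      list(backbone = list(widths = config$backbone$widths,
                           tap_blocks = config$backbone$tap_blocks,
                           weights_mode = config$backbone$weights_mode,
                           seed = config$backbone$seed,
                           k = config$backbone$k),
           preproc = unclass(config$preproc)),
      file.path(out, "features.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    artifacts <- c(artifacts, fpath, file.path(out, "features.json"))
  }
  cv_res <- NULL
  if ("classify" %in% config$stages) {
    if (is.null(feat)) stop("classify stage requires the features stage")
    cv_res <- evaluate_repeated_cv(feat$features, feat$labels, config$cv)
    jsonlite::write_json(
      list(summary = cv_res$summary, evaluations = cv_res$evaluations,
           panels = cv_res$panels, tuned_params = cv_res$tuned_params,
           dispersion_convention = cv_res$dispersion_convention,
           seed = config$cv$seed),
      file.path(out, "cv_result.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    artifacts <- c(artifacts, file.path(out, "cv_result.json"))
  }
  stats_out <- NULL
  if ("stats" %in% config$stages) {
    pts <- patient_mean_d(manifest)
    adj <- age_adjust(pts)
    stats_out <- list(
      n_case = sum(pts$group == "case"),
      n_control = sum(pts$group == "control"),
      control_age_slope = attr(adj, "control_slope"),
      average_d_auc = average_d_auc(pts)$auc,
      adjusted_d_auc = average_d_auc(adj, "adjusted_d")$auc,
      packyear_strata = packyear_subgroup_test(pts))
    if (nrow(pts) >= 10) {
      stats_out$ancova <- tryCatch(ancova_d(pts)$table, error = function(e) {
        list(error = conditionMessage(e))
      })
    }
    jsonlite::write_json(stats_out, file.path(out, "stats.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.csv(pts, file.path(out, "patient_d.csv"), row.names = FALSE)
    artifacts <- c(artifacts, file.path(out, "stats.json"),
                   file.path(out, "patient_d.csv"))
  }
  snapshot <- list(
    stages = config$stages,
    write_images = config$write_images,
    cohort = unclass(config$cohort),
    backbone = list(widths = config$backbone$widths,
                    tap_blocks = config$backbone$tap_blocks,
                    weights_mode = config$backbone$weights_mode,
                    seed = config$backbone$seed),
    preproc = unclass(config$preproc),
    cv = c(unclass(config$cv)[c("n_folds", "n_repeats", "seed", "n_keep",
                                "step_fraction", "num_trees_rfe",
                                "inner_folds", "selection")],
           list(rf_grid = config$cv$rf_grid)))
  jsonlite::write_json(snapshot, file.path(out, "config_snapshot.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  artifacts <- c(artifacts, file.path(out, "config_snapshot.json"))
  report <- list(
    package_version = as.character(utils::packageVersion("cspws")),
    stages_run = config$stages,
    artifacts = as.list(stats::setNames(
      as.character(tools::md5sum(artifacts[file.exists(artifacts)])),
      basename(artifacts[file.exists(artifacts)]))),
    cv_summary = if (!is.null(cv_res)) cv_res$summary else NULL,
    stats = if (!is.null(stats_out))
      stats_out[c("average_d_auc", "adjusted_d_auc")] else NULL)
  jsonlite::write_json(report, file.path(out, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
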