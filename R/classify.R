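## Supervised feature selection, random-forest tuning and repeated
## stratified cross-validation. Random forests are fit with ranger
## (single-threaded, seeded) so every result is reproducible.

.as_case_logical <- function(labels) {
  if (is.factor(labels)) {
    if (nlevels(labels) != 2) stop("labels must be binary")
    labels == levels(labels)[2]
  } else if (is.logical(labels)) {
    labels
  } else if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) stop("numeric labels must be 0/1")
    labels == 1
  } else if (is.character(labels)) {
    f <- factor(labels, levels = c("control", "case"))
    if (any(is.na(f))) stop("character labels must be control/case")
    f == "case"
  } else stop("unsupported label type")
}

#' Rank-based area under the ROC curve
#'
#' Mann-Whitney AUC: the probability that a random case scores above a
#' random control, with ties credited 1/2. Computed from midranks, which
#' is exactly the O(n^2) pairwise count `U / (n1 * n0)`.
#'
#' @param scores Numeric classifier scores (higher = more case-like).
#' @param labels Binary labels (factor control/case, logical, or 0/1).
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels) {
  pos <- .as_case_logical(labels)
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Youden-optimal operating point
#'
#' Scans all candidate thresholds (classify as case when score >=
#' threshold) and returns the one maximizing Youden's J = Se + Sp - 1;
#' ties resolve to the lowest threshold.
#'
#' @inheritParams roc_auc
#' @return List with `threshold`, `sensitivity`, `specificity`.
#' @export
youden_threshold <- function(scores, labels) {
  pos <- .as_case_logical(labels)
  if (!any(pos) || all(pos)) stop("both classes must be present")
  cand <- sort(unique(scores))
  se <- vapply(cand, function(t) mean(scores[pos] >= t), numeric(1))
  sp <- vapply(cand, function(t) mean(scores[!pos] < t), numeric(1))
  j <- se + sp - 1
  i <- which(j == max(j))[1]
  list(threshold = cand[i], sensitivity = se[i], specificity = sp[i])
}

.fit_ranger <- function(x, y, num_trees = 500, max_depth = 0,
                        min_node_size = 1, seed = 1, probability = TRUE,
                        importance = "none") {
  ranger::ranger(x = as.data.frame(x), y = y, num.trees = num_trees,
                 max.depth = max_depth, min.node.size = min_node_size,
                 probability = probability, importance = importance,
                 seed = seed, num.threads = 1)
}

.predict_case_prob <- function(fit, x) {
  p <- stats::predict(fit, as.data.frame(x), num.threads = 1)$predictions
  p[, "case"]
}

#' Recursive feature elimination with a random forest
#'
#' Iteratively fits a random forest, ranks features by impurity
#' importance, and drops the lowest-importance `step_fraction` of the
#' surviving features until `n_keep` remain. Deterministic given `seed`.
#'
#' @param features Numeric matrix (samples x features).
#' @param labels Binary labels.
#' @param n_keep Size of the retained panel (default 40).
#' @param step_fraction Fraction of surviving features dropped per round.
#' @param seed Integer seed.
#' @param num_trees Trees per elimination round.
#' @return A `cspws_selection`: list with `selected_indices` (ascending),
#'   `elimination_trace` (surviving counts per round) and `seed`.
#' @export
rfe_select <- function(features, labels, n_keep = 40, step_fraction = 0.2,
                       seed = 1, num_trees = 100) {
  stopifnot(is.matrix(features) || is.data.frame(features))
  features <- as.matrix(features)
  y <- factor(ifelse(.as_case_logical(labels), "case", "control"),
              levels = c("control", "case"))
  if (length(unique(y)) < 2) stop("labels are degenerate (single class)")
  p <- ncol(features)
  if (n_keep >= p) stop("n_keep (", n_keep, ") must be smaller than the ",
                        "feature count (", p, ")")
  surviving <- seq_len(p)
  trace <- integer(0)
  round_i <- 0
  while (length(surviving) > n_keep) {
    round_i <- round_i + 1
    trace <- c(trace, length(surviving))
    fit <- .fit_ranger(features[, surviving, drop = FALSE], y,
                       num_trees = num_trees, seed = seed + round_i,
                       probability = FALSE, importance = "impurity")
    imp <- fit$variable.importance
    n_drop <- min(max(1L, floor(length(surviving) * step_fraction)),
                  length(surviving) - n_keep)
    surviving <- surviving[order(imp, decreasing = TRUE)][
      seq_len(length(surviving) - n_drop)]
    surviving <- sort(surviving)
  }
  obj <- list(selected_indices = surviving,
              elimination_trace = c(trace, length(surviving)), seed = seed)
  class(obj) <- "cspws_selection"
  obj
}

#' Default random-forest tuning grid
#'
#' Trees in {100, 300, 500}, depth unbounded (0) or 8, minimum node size 1
#' or 3. Grid order defines tie-breaking priority.
#'
#' @return Data frame of parameter combinations.
#' @export
default_rf_grid <- function() {
  expand.grid(num_trees = c(100, 300, 500), max_depth = c(0, 8),
              min_node_size = c(1, 3), KEEP.OUT.ATTRS = FALSE)
}

## Stratified fold assignment: within each class, shuffled ids are dealt
## round-robin, so per-fold class counts differ by at most one.
.stratified_folds <- function(labels, k, seed) {
  pos <- .as_case_logical(labels)
  assign <- integer(length(labels))
  set.seed(seed)
  for (cl in c(FALSE, TRUE)) {
    ids <- which(pos == cl)
    ids <- ids[sample.int(length(ids))]
    assign[ids] <- rep_len(seq_len(k), length(ids))
  }
  assign
}

#' Grid-search tuning of the random-forest classifier
#'
#' Scores every grid row by the mean held-out AUC of an internal
#' stratified cross-validation on the supplied (training) data; ties break
#' in favour of the first-listed row.
#'
#' @param features Numeric matrix (samples x features).
#' @param labels Binary labels.
#' @param grid Data frame with columns `num_trees`, `max_depth`,
#'   `min_node_size`.
#' @param seed Integer seed.
#' @param inner_folds Folds of the internal CV (reduced if a class is
#'   smaller).
#' @return List with `params` (best row as a list), `scores` (mean inner
#'   AUC per row) and `grid`.
#' @export
tune_random_forest <- function(features, labels, grid = default_rf_grid(),
                               seed = 1, inner_folds = 3) {
  stopifnot(nrow(grid) >= 1)
  features <- as.matrix(features)
  y <- factor(ifelse(.as_case_logical(labels), "case", "control"),
              levels = c("control", "case"))
  k <- min(inner_folds, min(table(y)))
  if (k < 2) stop("classes too small for internal tuning CV")
  assign <- .stratified_folds(y, k, seed)
  scores <- numeric(nrow(grid))
  for (gi in seq_len(nrow(grid))) {
    aucs <- c()
    for (f in seq_len(k)) {
      tr <- assign != f
      if (length(unique(y[!tr])) < 2 || length(unique(y[tr])) < 2) next
      fit <- .fit_ranger(features[tr, , drop = FALSE], y[tr],
                         num_trees = grid$num_trees[gi],
                         max_depth = grid$max_depth[gi],
                         min_node_size = grid$min_node_size[gi],
                         seed = seed + 31 * gi + f)
      aucs <- c(aucs, roc_auc(.predict_case_prob(fit, features[!tr, , drop = FALSE]),
                              y[!tr]))
    }
    scores[gi] <- mean(aucs)
  }
  best <- which(scores == max(scores))[1]
  list(params = as.list(grid[best, , drop = FALSE]), scores = scores,
       grid = grid)
}

#' Cross-validation configuration
#'
#' Stratified four-fold cross-validation with five iterations by default
#' (20 evaluations). Feature selection and tuning run inside each
#' training fold (`selection = "nested"`, leakage-free); a `"pooled"`
#' mode selecting once on all data is available to mirror protocols that
#' select before cross-validation.
#'
#' @param n_folds,n_repeats Folds per repeat and number of repeats.
#' @param seed Master seed; per-repeat and per-fold seeds derive from it.
#' @param rf_grid Tuning grid (see [default_rf_grid()]).
#' @param n_keep Feature-panel size retained by RFE.
#' @param step_fraction RFE drop fraction per round.
#' @param num_trees_rfe Trees per RFE round.
#' @param inner_folds Internal tuning folds.
#' @param selection `"nested"` or `"pooled"`.
#' @return A `cspws_cv_config`.
#' @export
cv_config <- function(n_folds = 4, n_repeats = 5, seed = 1,
                      rf_grid = default_rf_grid(), n_keep = 40,
                      step_fraction = 0.2, num_trees_rfe = 100,
                      inner_folds = 3, selection = c("nested", "pooled")) {
  stopifnot(n_folds >= 2, n_repeats >= 1)
  obj <- list(n_folds = n_folds, n_repeats = n_repeats, stratified = TRUE,
              seed = seed, rf_grid = rf_grid, n_keep = n_keep,
              step_fraction = step_fraction, num_trees_rfe = num_trees_rfe,
              inner_folds = inner_folds, selection = match.arg(selection))
  class(obj) <- "cspws_cv_config"
  obj
}

#' Repeated stratified cross-validated evaluation
#'
#' For each repeat (with a distinct derived seed) patients are split into
#' stratified folds; within each training fold the RFE panel is selected,
#' the forest is grid-tuned and refit, held-out patients are scored, and
#' sensitivity/specificity are taken at the Youden-optimal threshold of
#' the training scores. Metrics are summarized as mean +/- SD across all
#' `n_folds * n_repeats` evaluations (the +/- convention recorded in the
#' result).
#'
#' @param features Numeric matrix (patients x features), rownames used as
#'   patient ids when present.
#' @param labels Binary labels (factor control/case recommended).
#' @param cfg A `cspws_cv_config`.
#' @return A `cspws_cv_result`: `evaluations` data frame (repeat, fold,
#'   auc, sensitivity, specificity, threshold), `panels`, `tuned_params`,
#'   `train_ids`/`test_ids` per evaluation, and `summary` (mean and sd per
#'   metric).
#' @export
evaluate_repeated_cv <- function(features, labels, cfg = cv_config()) {
  features <- as.matrix(features)
  y <- factor(ifelse(.as_case_logical(labels), "case", "control"),
              levels = c("control", "case"))
  if (min(table(y)) < cfg$n_folds) {
    stop("each class needs at least n_folds = ", cfg$n_folds, " members")
  }
  ids <- rownames(features)
  if (is.null(ids)) ids <- sprintf("S%03d", seq_len(nrow(features)))
  pooled_sel <- NULL
  if (cfg$selection == "pooled") {
    pooled_sel <- rfe_select(features, y, n_keep = cfg$n_keep,
                             step_fraction = cfg$step_fraction,
                             seed = cfg$seed, num_trees = cfg$num_trees_rfe)
  }
  evals <- list()
  panels <- list()
  tuned_all <- list()
  train_ids <- list()
  test_ids <- list()
  for (r in seq_len(cfg$n_repeats)) {
    rep_seed <- cfg$seed + 1000L * r
    assign <- .stratified_folds(y, cfg$n_folds, rep_seed)
    for (f in seq_len(cfg$n_folds)) {
      te <- assign == f
      tr <- !te
      sel <- if (is.null(pooled_sel)) {
        rfe_select(features[tr, , drop = FALSE], y[tr],
                   n_keep = cfg$n_keep, step_fraction = cfg$step_fraction,
                   seed = rep_seed + f, num_trees = cfg$num_trees_rfe)
      } else pooled_sel
      xs_tr <- features[tr, sel$selected_indices, drop = FALSE]
      xs_te <- features[te, sel$selected_indices, drop = FALSE]
      tuned <- tune_random_forest(xs_tr, y[tr], grid = cfg$rf_grid,
                                  seed = rep_seed + 100 + f,
                                  inner_folds = cfg$inner_folds)
      fit <- .fit_ranger(xs_tr, y[tr],
                         num_trees = tuned$params$num_trees,
                         max_depth = tuned$params$max_depth,
                         min_node_size = tuned$params$min_node_size,
                         seed = rep_seed + 200 + f)
      tr_scores <- .predict_case_prob(fit, xs_tr)
      te_scores <- .predict_case_prob(fit, xs_te)
      op <- youden_threshold(tr_scores, y[tr])
      pos_te <- y[te] == "case"
      evals[[length(evals) + 1]] <- data.frame(
        repeat_i = r, fold = f,
        auc = roc_auc(te_scores, y[te]),
        sensitivity = mean(te_scores[pos_te] >= op$threshold),
        specificity = mean(te_scores[!pos_te] < op$threshold),
        threshold = op$threshold)
      panels[[length(panels) + 1]] <- sel$selected_indices
      tuned_all[[length(tuned_all) + 1]] <- tuned$params
      train_ids[[length(train_ids) + 1]] <- ids[tr]
      test_ids[[length(test_ids) + 1]] <- ids[te]
    }
  }
  ev <- do.call(rbind, evals)
  summ <- data.frame(
    metric = c("auc", "sensitivity", "specificity"),
    mean = c(mean(ev$auc), mean(ev$sensitivity), mean(ev$specificity)),
    sd = c(stats::sd(ev$auc), stats::sd(ev$sensitivity),
           stats::sd(ev$specificity)))
  obj <- list(evaluations = ev, panels = panels, tuned_params = tuned_all,
              train_ids = train_ids, test_ids = test_ids, summary = summ,
              config = cfg,
              dispersion_convention = "sd over n_folds x n_repeats evaluations")
  class(obj) <- "cspws_cv_result"
  obj
}

#' @export
print.cspws_cv_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("repeated stratified CV (%d x %d): AUC %.2f +/- %.2f, Se %.0f%%, Sp %.0f%%\n",
              x$config$n_folds, x$config$n_repeats,
              s$mean[s$metric == "auc"], s$sd[s$metric == "auc"],
              100 * s$mean[s$metric == "sensitivity"],
              100 * s$mean[s$metric == "specificity"]))
  invisible(x)
}
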