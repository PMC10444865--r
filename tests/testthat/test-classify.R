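## Brute-force pairwise AUC oracle.
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  u <- 0
  for (p in pos) u <- u + sum(p > neg) + 0.5 * sum(p == neg)
  u / (length(pos) * length(neg))
}

test_that("rank AUC matches its definition and the pairwise oracle", {
  expect_equal(roc_auc(c(1, 2, 10, 11), c(0, 0, 1, 1)), 1)
  expect_equal(roc_auc(rep(3, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  set.seed(4)
  for (i in 1:10) {
    n <- sample(10:200, 1)
    sc <- round(rnorm(n), 1)        # ties likely
    lb <- rbinom(n, 1, 0.4)
    if (sum(lb) == 0 || sum(lb) == n) next
    expect_identical(roc_auc(sc, lb), auc_oracle(sc, lb))
  }
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("Youden operating point agrees with an exhaustive threshold scan", {
  sep <- youden_threshold(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(sep$sensitivity, 1)
  expect_equal(sep$specificity, 1)
  deg <- youden_threshold(rep(0.5, 6), c(0, 1, 0, 1, 0, 1))
  expect_equal(deg$sensitivity + deg$specificity, 1)
  sc <- c(0.1, 0.4, 0.35, 0.8)
  lb <- c(0, 0, 1, 1)
  got <- youden_threshold(sc, lb)
  cand <- sort(unique(sc))
  j <- sapply(cand, function(t) {
    mean(sc[lb == 1] >= t) + mean(sc[lb == 0] < t) - 1
  })
  best <- cand[which(j == max(j))[1]]
  expect_equal(got$threshold, best)
  expect_equal(got$sensitivity + got$specificity - 1, max(j))
})

test_that("RFE returns exactly the requested panel, deterministically", {
  set.seed(11)
  x <- matrix(rnorm(60 * 200), 60, 200)
  y <- factor(rep(c("control", "case"), 30), levels = c("control", "case"))
  sel1 <- rfe_select(x, y, n_keep = 40, seed = 3)
  sel2 <- rfe_select(x, y, n_keep = 40, seed = 3)
  expect_length(sel1$selected_indices, 40)
  expect_identical(sel1$selected_indices, sel2$selected_indices)
  expect_false(is.unsorted(sel1$selected_indices))
  expect_true(all(diff(sel1$elimination_trace) < 0))
  expect_equal(sel1$elimination_trace[1], 200)
  expect_equal(tail(sel1$elimination_trace, 1), 40)
  expect_error(rfe_select(x, y, n_keep = 300, seed = 1), "smaller")
  expect_error(rfe_select(x, factor(rep("case", 60)), n_keep = 10), "binary|single|degenerate")
})

test_that("grid tuning scores by inner CV and breaks ties by grid order", {
  set.seed(21)
  ## cleanly separable data: every grid row reaches AUC 1, first row wins
  x <- rbind(matrix(rnorm(20 * 5, -3), 20, 5), matrix(rnorm(20 * 5, 3), 20, 5))
  y <- factor(rep(c("control", "case"), each = 20),
              levels = c("control", "case"))
  grid <- data.frame(num_trees = c(100, 300), max_depth = 0,
                     min_node_size = 1)
  tuned <- tune_random_forest(x, y, grid, seed = 2)
  expect_equal(max(tuned$scores), 1)
  expect_equal(tuned$params$num_trees, 100)
  single <- data.frame(num_trees = 250, max_depth = 4, min_node_size = 2)
  got <- tune_random_forest(x, y, single, seed = 2)
  expect_equal(got$params$num_trees, 250)
  expect_identical(tune_random_forest(x, y, grid, seed = 5)$scores,
                   tune_random_forest(x, y, grid, seed = 5)$scores)
})

test_that("repeated CV respects the protocol on a small informative problem", {
  set.seed(31)
  n <- 24
  x <- matrix(rnorm(n * 30), n, 30)
  y <- factor(rep(c("control", "case"), each = n / 2),
              levels = c("control", "case"))
  x[y == "case", 1:3] <- x[y == "case", 1:3] + 2
  rownames(x) <- sprintf("P%02d", 1:n)
  cfg <- cv_config(n_folds = 3, n_repeats = 2, seed = 9, n_keep = 10,
                   rf_grid = data.frame(num_trees = 100, max_depth = 0,
                                        min_node_size = 1))
  res <- evaluate_repeated_cv(x, y, cfg)
  expect_equal(nrow(res$evaluations), 6)
  for (i in seq_along(res$train_ids)) {
    expect_length(intersect(res$train_ids[[i]], res$test_ids[[i]]), 0)
    expect_setequal(c(res$train_ids[[i]], res$test_ids[[i]]), rownames(x))
  }
  res2 <- evaluate_repeated_cv(x, y, cfg)
  expect_identical(res$evaluations, res2$evaluations)
  expect_gt(res$summary$mean[res$summary$metric == "auc"], 0.7)
  expect_error(evaluate_repeated_cv(x[1:5, ], y[1:5], cfg), "n_folds")
})

test_that("pooled selection mode reuses one panel across evaluations", {
  set.seed(41)
  n <- 24
  x <- matrix(rnorm(n * 40), n, 40)
  y <- factor(rep(c("control", "case"), each = n / 2),
              levels = c("control", "case"))
  cfg <- cv_config(n_folds = 3, n_repeats = 2, seed = 5, n_keep = 8,
                   selection = "pooled",
                   rf_grid = data.frame(num_trees = 100, max_depth = 0,
                                        min_node_size = 1))
  res <- evaluate_repeated_cv(x, y, cfg)
  expect_equal(nrow(res$evaluations), 6)
  for (p in res$panels) expect_identical(p, res$panels[[1]])
  ## nested mode re-selects per training fold
  cfg_n <- cv_config(n_folds = 3, n_repeats = 2, seed = 5, n_keep = 8,
                     rf_grid = cfg$rf_grid)
  res_n <- evaluate_repeated_cv(x, y, cfg_n)
  expect_gt(length(unique(res_n$panels)), 1)
})
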