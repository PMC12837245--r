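test_that("accuracy matches direct misclassification counting", {
  cm <- confusion_matrix(rep(c("hypertensive", "normal"), c(50, 50)),
                         rep(c("hypertensive", "normal"), c(50, 50)))
  expect_identical(accuracy(cm), 100)
  truth <- c(rep("hypertensive", 30), rep("normal", 34))
  pred <- c(rep("hypertensive", 30), rep("hypertensive", 3), rep("normal", 31))
  cm2 <- confusion_matrix(truth, pred)
  expect_identical(c(cm2$TP, cm2$TN, cm2$FP, cm2$FN), c(30L, 31L, 3L, 0L))
  expect_equal(accuracy(cm2), 95.3125)
  # equals 100 * (1 - direct misclassification rate)
  expect_equal(accuracy(cm2), 100 * mean(truth == pred))
  cm3 <- structure(list(TP = 25L, TN = 25L, FP = 25L, FN = 25L),
                   class = "confusion_matrix")
  expect_identical(accuracy(cm3), 50)
  cm0 <- structure(list(TP = 0L, TN = 0L, FP = 0L, FN = 0L),
                   class = "confusion_matrix")
  expect_error(accuracy(cm0), "empty")
})

test_that("subject folds partition each class evenly", {
  subj <- sprintf("S%02d", 1:23)
  lab <- factor(rep(c("normal", "hypertensive"), c(12, 11)),
                levels = c("normal", "hypertensive"))
  folds <- bcghyper:::stratified_folds(subj, lab, 5L, seed = 3L)
  expect_identical(sort(unlist(folds)), sort(subj))     # every subject once
  sizes <- lengths(folds)
  expect_lte(max(sizes) - min(sizes), 2L)
  for (f in folds) {
    expect_lte(abs(sum(lab[match(f, subj)] == "normal") -
                     sum(lab[match(f, subj)] == "hypertensive")), 2L)
  }
})

test_that("cross-validation respects the partition contract", {
  segs <- small_segments(n_per_class = 6L, duration = 30, seed = 13L)
  res <- cross_validate(segs, "raw", "none", "nbc", folds = 3L, seed = 2L)
  tested <- unlist(res$fold_subjects)
  expect_identical(sort(tested), sort(unique(segs$subject_ids)))
  expect_identical(length(res$folds), 3L)
  expect_equal(res$mean_accuracy, mean(res$fold_accuracies))
  # same seed reproduces the result
  res2 <- cross_validate(segs, "raw", "none", "nbc", folds = 3L, seed = 2L)
  expect_identical(res$fold_accuracies, res2$fold_accuracies)
  expect_error(cross_validate(segs, "raw", "none", "nbc", folds = 10L),
               "per class")
})

test_that("results grid covers the full cartesian and tracks the best cell", {
  segs <- small_segments(n_per_class = 5L, duration = 30, seed = 14L)
  grid <- suppressWarnings(results_grid(
    segs, extractors = c("raw", "modwt"), selectors = c("ig", "pcc"),
    classifiers = c("nbc", "dt"), folds = 2L, seed = 3L,
    opts = list(modwt_levels = 3L)))
  expect_identical(nrow(grid$grid), 8L)
  expect_false(any(is.na(grid$grid$mean_accuracy)))
  expect_identical(grid$best$mean_accuracy, max(grid$grid$mean_accuracy))
})

test_that("cohen kappa hits its fixed points", {
  y <- rep(c("normal", "hypertensive"), each = 20)
  expect_identical(cohen_kappa(y, y), 1)
  set.seed(4)
  chance <- vapply(1:200, function(i) cohen_kappa(y, sample(y)), 0)
  expect_lt(abs(mean(chance)), 0.05)
})

test_that("feature statistics match rank-arithmetic oracles", {
  # fully separated two-group sample with hand-computable ranks
  x <- c(1, 2, 3, 4, 10, 11, 12, 13)
  g <- factor(rep(c("normal", "hypertensive"), each = 4),
              levels = c("normal", "hypertensive"))
  kw <- stats::kruskal.test(x, g)
  oracle <- 12 / (8 * 9) * (sum(1:4)^2 / 4 + sum(5:8)^2 / 4) - 3 * 9
  expect_equal(unname(kw$statistic), oracle, tolerance = 1e-10)
  tab <- feature_table(cbind(f = x, g2 = c(1, 5, 2, 6, 3, 7, 4, 8)), g)
  st <- feature_statistics(tab, knn_k = 3L, folds = 2L, seed = 2L)
  expect_equal(st$per_feature$kw_stat[1], oracle, tolerance = 1e-10)
  expect_lt(st$per_feature$kw_p[1], 0.05)
  expect_false(is.null(st$friedman))
  expect_true(is.finite(st$kappa))
})

test_that("constant features are skipped with a note in the statistics", {
  y <- rep(c(0, 1), each = 10)
  tab <- feature_table(cbind(k = rep(1, 20), x = rnorm(20)), y)
  st <- feature_statistics(tab, knn_k = 3L, folds = 2L)
  expect_identical(st$skipped, "k")
  expect_true(is.na(st$per_feature$kw_stat[1]))
})
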