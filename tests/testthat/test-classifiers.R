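test_that("maximum-uncertainty regularization follows the max rule", {
  expect_equal(regularize_spectrum(c(4, 2, 0.1, 0.1)), c(4, 2, 1.55, 1.55))
  lam <- c(10, 5, 1, 0.01)
  reg <- regularize_spectrum(lam)
  expect_true(all(reg >= mean(lam)))
  expect_identical(reg[lam >= mean(lam)], lam[lam >= mean(lam)])
})

test_that("mulda with a spherical within-scatter equals plain LDA", {
  set.seed(3)
  n <- 60
  X <- rbind(matrix(rnorm(n * 3), n, 3),
             sweep(matrix(rnorm(n * 3), n, 3), 2, c(3, 1, 0), "+"))
  y <- factor(rep(c("normal", "hypertensive"), each = n),
              levels = c("normal", "hypertensive"))
  # whiten by the sample within-scatter so M_q is exactly spherical
  sc <- bcghyper:::scatter_matrices(X, y)
  ei <- eigen(sc$Mw / (2 * n - 2), symmetric = TRUE)
  Xw <- X %*% (ei$vectors %*% diag(1 / sqrt(ei$values)) %*% t(ei$vectors))
  m <- mulda_fit(feature_table(Xw, y))
  expect_lt(diff(range(m$eigenvalues)), 1e-10)
  expect_equal(m$eigenvalues_reg, m$eigenvalues)        # regularizer a no-op
  ld <- MASS::lda(Xw, grouping = y)
  v_lda <- ld$scaling[, 1] / sqrt(sum(ld$scaling[, 1]^2))
  expect_lt(abs(abs(sum(m$discriminants[, 1] * v_lda)) - 1), 1e-8)
})

test_that("mulda separates two well-separated Gaussian classes", {
  set.seed(12)
  X <- rbind(matrix(rnorm(100 * 2, 0), 100, 2), matrix(rnorm(100 * 2, 3), 100, 2))
  tab <- feature_table(X, rep(c(0, 1), each = 100))
  m <- mulda_fit(tab)
  expect_identical(ncol(m$discriminants), 1L)
  expect_gte(mean(predict(m, X) == tab$labels), 0.95)
  expect_error(mulda_fit(feature_table(X[1:2, ], c(0, 1))), "samples")
})

test_that("adaboost voting weights follow the half-log-odds formula", {
  expect_identical(0.5 * log((1 - 0.5) / 0.5), 0)
  expect_equal(0.5 * log((1 - 0.1) / 0.1), 0.5 * log(9))
  tab <- generate_feature_table(synth_table_config(
    n_samples = 100L, d_informative = 3L, d_noise = 5L, effect_size = 1.5,
    seed = 4L))
  ens <- hybrid_adaboost_mulda(tab, T = 10L, seed = 2L)
  expect_equal(ens$alphas, 0.5 * log((1 - ens$epsilons) / ens$epsilons))
})

test_that("boosting keeps weights normalized and obeys the training bound", {
  for (s in 1:3) {
    tab <- generate_feature_table(synth_table_config(
      n_samples = 80L, d_informative = 3L, d_noise = 5L, effect_size = 1.5,
      seed = s))
    ens <- hybrid_adaboost_mulda(tab, T = 8L, seed = s)
    for (D in ens$weight_history) {
      expect_true(all(D >= 0))
      expect_lt(abs(sum(D) - 1), 1e-12)
    }
    tr_err <- mean(predict(ens, tab) != tab$labels)
    expect_lte(tr_err, boosting_bound(ens) + 1e-12)
  }
})

test_that("single-round hybrids equal their base learner", {
  tab <- generate_feature_table(synth_table_config(
    n_samples = 80L, d_informative = 2L, d_noise = 4L, effect_size = 1.5,
    seed = 9L))
  e1 <- hybrid_adaboost_mulda(tab, T = 1L, seed = 9L)
  expect_identical(e1$T, 1L)
  expect_identical(predict(e1, tab),
                   factor(predict(e1$models[[1]], tab$values),
                          levels = levels(tab$labels)))
  e2 <- hybrid_adaboost_rf(tab, T = 1L, n_trees = 10L, seed = 9L)
  expect_identical(predict(e2, tab),
                   factor(unname(e2$base_predict(e2$models[[1]], tab$values)),
                          levels = levels(tab$labels)))
})

test_that("boosted weak forests fit training data at least as well as one", {
  worse <- 0L
  for (s in 1:10) {
    tab <- generate_feature_table(synth_table_config(
      n_samples = 80L, d_informative = 3L, d_noise = 5L, effect_size = 1,
      seed = s))
    ens <- hybrid_adaboost_rf(tab, T = 10L, n_trees = 10L, max_nodes = 4L,
                              seed = s)
    e_ens <- mean(predict(ens, tab) != tab$labels)
    single <- bcghyper:::with_local_seed(s, randomForest::randomForest(
      x = tab$values, y = tab$labels, ntree = 10L, maxnodes = 4L))
    e_single <- mean(predict(single, tab$values) != tab$labels)
    if (e_ens > e_single) worse <- worse + 1L
  }
  expect_identical(worse, 0L)
})

test_that("degenerate all-identical tables error rather than crash", {
  X <- matrix(1, 10, 3)
  expect_error(hybrid_adaboost_rf(feature_table(X, rep(c(0, 1), 5)), T = 2L),
               "degenerate")
  expect_error(baseline_classifier(feature_table(X[1, , drop = FALSE], 0),
                                   "nbc"), "two")
})

test_that("arima features recover known processes", {
  set.seed(8)
  ar1 <- as.numeric(stats::arima.sim(list(ar = 0.7), 2000))
  spec_fit <- arima_features(ar1, c(1L, 0L, 0L))
  expect_gt(spec_fit$features[["phi1"]], 0.6)
  expect_lt(spec_fit$features[["phi1"]], 0.8)
  # independent Yule-Walker oracle
  yw <- stats::acf(ar1, lag.max = 1, plot = FALSE)$acf[2]
  expect_lt(abs(spec_fit$features[["phi1"]] - yw), 0.05)
  # white-noise nulls (separate AR and MA fits; joint ARMA is unidentifiable)
  set.seed(10)
  wn <- rnorm(2000)
  expect_lt(max(abs(arima_features(wn, c(2L, 0L, 0L))$features[1:2])), 0.1)
  expect_lt(max(abs(arima_features(wn, c(0L, 0L, 2L))$features[1:2])), 0.1)
  # differencing removes a linear trend exactly
  expect_true(all(diff(0.5 * (1:100)) == 0.5))
  expect_error(arima_features(rnorm(10), c(2L, 1L, 2L)), "short")
  expect_identical(length(arima_features(ar1, c(2L, 1L, 2L))$features), 6L)
})

test_that("arima-adaboost rounds behave per the regression-boosting rules", {
  # beta = 1 (eps = 0.5) gives zero connection weight
  expect_identical(0.5 * log(1 / (0.5 / (1 - 0.5))), 0)
  tab <- generate_feature_table(synth_table_config(
    n_samples = 80L, d_informative = 3L, d_noise = 3L, effect_size = 2.5,
    seed = 3L))
  m <- hybrid_arima_adaboost(tab, segments = NULL, T = 10L, seed = 3L)
  expect_gt(length(m$models), 0L)
  expect_true(all(m$epsilons < 0.5))
  pred <- predict(m, tab)
  expect_gte(mean(pred == tab$labels), 0.9)
  sc <- predict(m, tab, type = "score")
  expect_true(all(sc >= 0 & sc <= 1))
})

test_that("time weighting follows its exponential decay", {
  expect_identical(time_weight(0, 0.5), 1)
  expect_identical(time_weight(0, 0), 1)
  expect_equal(time_weight(1, 0.5), exp(-0.5), tolerance = 1e-12)
  expect_equal(time_weight(1, 0.5), 0.6065, tolerance = 1e-4)
  expect_error(time_weight(1, 0.7), "eta")
})

test_that("tw-hasvm with eta = 0 equals a plain adaboost of SVMs", {
  tab <- generate_feature_table(synth_table_config(
    n_samples = 80L, d_informative = 2L, d_noise = 4L, effect_size = 1,
    seed = 6L))
  seed <- 5L
  T_rounds <- 6L
  tw <- tw_hasvm_fit(tab, eta = 0, batch_index = 1L, T = T_rounds, seed = seed)
  # side-by-side oracle: the same boosting-of-SVMs loop written out plainly,
  # with no time-weight machinery at all
  X <- tab$values
  y <- droplevels(tab$labels)
  n <- nrow(X)
  w <- rep(1 / n, n)
  alphas <- numeric()
  preds <- matrix(NA_character_, n, 0)
  for (t in seq_len(T_rounds)) {
    w <- w / sum(w)
    idx <- bcghyper:::weighted_resample(n, w, y, bcghyper:::derive_seed(seed, t))
    Ct <- e1071::svm(x = X[idx, , drop = FALSE], y = y[idx],
                     kernel = "polynomial", degree = 3L, cost = 1,
                     scale = FALSE)
    p <- predict(Ct, X)
    e <- sum(w[p != y])
    if (e >= 0.5) break
    e <- max(e, 1e-10)
    alpha <- 0.5 * log((1 - e) / e)
    alphas <- c(alphas, alpha)
    preds <- cbind(preds, as.character(p))
    w <- w * exp(alpha * (p != y))
    if (e <= 1e-10) break
  }
  expect_equal(tw$alphas, alphas)
  score <- as.vector((preds == "hypertensive") %*% alphas -
                       (preds == "normal") %*% alphas)
  oracle_pred <- ifelse(score > 0, "hypertensive", "normal")
  expect_identical(as.character(predict(tw, tab)), oracle_pred)
})

test_that("tw-hasvm prediction is the weighted per-class vote", {
  tab <- generate_feature_table(synth_table_config(
    n_samples = 60L, d_informative = 2L, d_noise = 2L, effect_size = 2,
    seed = 7L))
  m1 <- tw_hasvm_fit(tab, T = 1L, seed = 2L)
  expect_identical(predict(m1, tab),
                   factor(unname(predict(m1$learners[[1]], tab$values)),
                          levels = levels(tab$labels)))
  # two disagreeing learners: the heavier alpha wins
  fake <- m1
  fake$learners <- list(m1$learners[[1]], m1$learners[[1]])
  fake$alphas <- c(2, 1)
  expect_identical(predict(fake, tab), predict(m1, tab))
})

test_that("gaussian naive Bayes approaches the analytic Bayes accuracy", {
  set.seed(9)
  X <- matrix(c(rnorm(1000, -2), rnorm(1000, 2)), ncol = 1)
  tab <- feature_table(X, rep(c(0, 1), each = 1000))
  nb <- baseline_classifier(tab, "nbc")
  acc <- mean(predict(nb, tab) == tab$labels)
  expect_lt(abs(acc - pnorm(2)), 0.02)
})

test_that("baseline classifiers are reproducible and validated", {
  tab <- generate_feature_table(synth_table_config(
    n_samples = 60L, d_informative = 2L, d_noise = 2L, effect_size = 2,
    seed = 8L))
  for (m in c("rf", "dt", "nbc", "adaboost")) {
    p1 <- predict(baseline_classifier(tab, m, seed = 4L), tab)
    p2 <- predict(baseline_classifier(tab, m, seed = 4L), tab)
    expect_identical(p1, p2)
  }
  expect_error(baseline_classifier(tab, "svm"), "arg")
})
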