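test_that("information gain matches direct entropy arithmetic", {
  # feature identical to balanced labels carries the full class entropy
  y <- rep(c(0, 1), each = 50)
  tab <- feature_table(cbind(flab = y, fnoise = seq_len(100) %% 7),
                       y)
  ig <- information_gain(tab, bins = 10L)
  expect_equal(ig$scores[["flab"]], 1)
  # oracle on the exact discretized table
  f <- bcghyper:::equal_freq_bins(tab$values[, 2], 10L)
  expect_equal(ig$scores[["fnoise"]], oracle_ig(f, tab$labels),
               tolerance = 1e-12)
  # constant feature has zero gain
  tabc <- feature_table(cbind(k = rep(1, 100), x = rnorm(100)), y)
  expect_identical(information_gain(tabc)$scores[["k"]], 0)
  expect_error(information_gain(feature_table(cbind(a = rnorm(10)),
                                              rep(0, 10))), "classes")
})

test_that("information gain is bounded by the class entropy", {
  for (s in 1:5) {
    set.seed(s)
    n <- 60
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    tab <- feature_table(matrix(rnorm(n * 4), n, 4), y)
    ig <- information_gain(tab)
    hp <- oracle_entropy(table(y) / n)
    expect_true(all(ig$scores >= -1e-12 & ig$scores <= hp + 1e-12))
  }
})

test_that("V-shaped transfer satisfies its fixed points and monotonicity", {
  expect_identical(vshape_transfer(0), 0)
  expect_equal(vshape_transfer(1), (2 / pi) * atan(pi / 2), tolerance = 1e-12)
  expect_equal(vshape_transfer(1), 0.6390929, tolerance = 1e-6)
  expect_gt(1 - vshape_transfer(1e8), 0)
  expect_lt(1 - vshape_transfer(1e8), 1e-7)
  t_grid <- seq(0, 50, length.out = 200)
  expect_true(all(diff(vshape_transfer(t_grid)) >= 0))
  expect_equal(vshape_transfer(-3), vshape_transfer(3))
})

test_that("wrapper fitness combines error and selection ratio as specified", {
  tab <- generate_feature_table(synth_table_config(n_samples = 60L,
                                                   d_informative = 2L,
                                                   d_noise = 2L,
                                                   effect_size = 4,
                                                   seed = 8L))
  ev <- fitness_evaluator(tab, k1 = 0.99, k2 = 0.01, seed = 3L)
  f_all <- selection_fitness(rep(1, 4), ev)
  # arithmetic identity: fitness = k1*error + k2*FSR, recovered exactly
  err_all <- (f_all - 0.01 * 1) / 0.99
  expect_gte(err_all, 0)
  expect_equal(selection_fitness(rep(1, 4), ev), f_all)   # memoized, stable
  # direct arithmetic case of the weighting rule
  expect_equal(0.99 * 0.1 + 0.01 * 0.5, 0.104)
  expect_error(selection_fitness(rep(0, 4), ev), "no features")
})

test_that("wrapper selectors find the exhaustive optimum on tiny tables", {
  tab <- toy_d3_table(seed = 11L)
  for (s in 1:3) {
    ev <- fitness_evaluator(tab, seed = s)
    brute <- oracle_brute_force_fitness(tab, ev)
    expect_equal(btsa_select(tab, ev, pop = 8L, generations = 30L,
                             seed = s)$fitness, brute)
    expect_equal(aoa_select(tab, ev, pop = 8L, generations = 30L,
                            seed = s)$fitness, brute)
    expect_equal(baseline_select(tab, "bpso", ev, pop = 8L, generations = 30L,
                                 seed = s)$fitness, brute)
  }
})

test_that("selector runs are elitist and bit-reproducible", {
  tab <- generate_feature_table(synth_table_config(n_samples = 60L,
                                                   d_informative = 2L,
                                                   d_noise = 6L,
                                                   effect_size = 2, seed = 4L))
  for (fn in list(btsa_select, aoa_select)) {
    r1 <- fn(tab, fitness_evaluator(tab, seed = 5L), pop = 10L,
             generations = 15L, seed = 5L)
    r2 <- fn(tab, fitness_evaluator(tab, seed = 5L), pop = 10L,
             generations = 15L, seed = 5L)
    expect_identical(r1$mask, r2$mask)
    expect_identical(r1$trace, r2$trace)
    expect_true(all(diff(r1$trace) <= 0))
    expect_gt(sum(r1$mask), 0)
    # elitism never returns worse than the all-features mask
    ev <- fitness_evaluator(tab, seed = 5L)
    expect_lte(r1$fitness, selection_fitness(rep(1, 8), ev) + 1e-12)
  }
})

test_that("a perfectly predictive feature drives fitness to k2/d", {
  set.seed(9)
  y <- rep(c(0, 1), each = 30)
  X <- cbind(y * 10 - 5, matrix(rnorm(60 * 3), 60, 3))
  colnames(X) <- c("perfect", "n1", "n2", "n3")
  tab <- feature_table(X, y)
  for (sel in c("btsa", "aoa", "bpso", "baco")) {
    ev <- fitness_evaluator(tab, seed = 2L)
    res <- switch(sel,
      btsa = btsa_select(tab, ev, pop = 10L, generations = 25L, seed = 2L),
      aoa = aoa_select(tab, ev, pop = 10L, generations = 25L, seed = 2L),
      bpso = baseline_select(tab, "bpso", ev, pop = 10L, generations = 25L,
                             seed = 2L),
      baco = baseline_select(tab, "baco", ev, pop = 10L, generations = 25L,
                             seed = 2L))
    expect_lte(res$fitness, 0.01 * (1 / 4) + 1e-9)
  }
})

test_that("filter baselines score association sensibly", {
  set.seed(10)
  y <- rep(c(0, 1), each = 40)
  X <- cbind(lab = y, const = rep(2, 80), noise = rnorm(80))
  tab <- feature_table(X, y)
  chi <- baseline_select(tab, "chi2")
  expect_identical(chi$scores[["const"]], 0)
  expect_identical(chi$mask[[2]], 0L)
  pcc <- baseline_select(tab, "pcc")
  expect_equal(pcc$scores[["lab"]], 1)
  expect_identical(pcc$scores[["const"]], 0)
  expect_identical(which.max(pcc$scores), c(lab = 1L))
  expect_error(baseline_select(tab, "mrmr"), "arg")
})

test_that("levy scale constant matches its gamma-function closed form", {
  alpha <- 0.5
  oracle <- gamma(1 + alpha) * sin(pi * alpha / 2) /
    (gamma((1 + alpha) / 2) * alpha * 2^((alpha - 1) / 2))
  expect_equal(levy_sigma(0.5), oracle, tolerance = 1e-12)
  expect_equal(levy_sigma(0.5), 1.2166, tolerance = 1e-3)
})
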