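test_that("cohort records have the configured length and are seed-deterministic", {
  cfg <- synth_cohort_config(n_normal = 2L, n_hyper = 2L, duration = 30,
                             seed = 7L)
  coh <- generate_bcg_cohort(cfg)
  expect_length(coh, 4L)
  expect_true(all(vapply(coh, function(r) length(r$channels[[1]]), 0) == 3000))
  expect_identical(coh, generate_bcg_cohort(cfg))
  # 5-minute records at 100 Hz carry 30,000 samples
  full <- generate_bcg_cohort(synth_cohort_config(n_normal = 1L, n_hyper = 1L,
                                                  seed = 1L))
  expect_length(full[[1]]$channels[[1]], 30000L)
})

test_that("invalid cohort configurations are rejected", {
  expect_error(synth_cohort_config(fs = 0), "fs")
  expect_error(synth_cohort_config(duration = -1), "duration")
  expect_error(synth_cohort_config(n_normal = 0L), "counts")
  expect_error(synth_cohort_config(hr_sd_normal = -1), "SD")
})

test_that("no-contrast configuration gives identical class pulse morphology", {
  pn <- bcghyper:::pulse_params("normal", 1)
  ph <- bcghyper:::pulse_params("hypertensive", 1)
  expect_identical(pn, ph)
  # and with contrast the hypertensive pulse is larger and narrower
  ph2 <- bcghyper:::pulse_params("hypertensive", 1.5)
  expect_gt(ph2$amp, pn$amp)
  expect_lt(ph2$width, pn$width)
})

test_that("mean inter-beat interval tracks the class heart rate", {
  cfg <- synth_cohort_config(n_normal = 60L, n_hyper = 1L, duration = 120,
                             hr_sd_normal = 8.3, seed = 21L)
  coh <- generate_bcg_cohort(cfg)
  ibis <- vapply(coh[seq_len(60)], function(r) mean(diff(r$beat_times)), 0)
  # per-record mean IBI averages to 60/hr_mean; SE from the between-record SD
  se <- stats::sd(ibis) / sqrt(length(ibis))
  expect_lt(abs(mean(ibis) - 60 / cfg$hr_mean_normal), 3 * se + 0.02)
})

test_that("feature table has the configured class contrast and clean noise", {
  cfg <- synth_table_config(n_samples = 2000L, d_informative = 3L,
                            d_noise = 4L, effect_size = 2, seed = 3L)
  tab <- generate_feature_table(cfg)
  expect_identical(tab, generate_feature_table(cfg))
  expect_equal(as.vector(table(tab$labels)), c(1000L, 1000L))
  for (j in 1:3) {
    d <- mean(tab$values[tab$labels == "hypertensive", j]) -
      mean(tab$values[tab$labels == "normal", j])
    expect_lt(abs(d - 2), 3 * sqrt(2 / 1000))
  }
  for (j in 4:7) {
    d <- mean(tab$values[tab$labels == "hypertensive", j]) -
      mean(tab$values[tab$labels == "normal", j])
    expect_lt(abs(d), 3 * sqrt(2 / 1000))
  }
  expect_true(all(grepl("^inf", tab$feature_names[1:3])))
  expect_true(all(grepl("^noise", tab$feature_names[4:7])))
})

test_that("informative columns alone support accurate k-NN classification", {
  tab <- generate_feature_table(synth_table_config(
    n_samples = 200L, d_informative = 5L, d_noise = 15L, effect_size = 2,
    seed = 5L))
  acc <- oracle_knn_cv(tab$values[, 1:5], tab$labels, k = 10L, seed = 5L)
  expect_gte(acc, 0.90)
})

test_that("zero effect size carries no class information", {
  accs <- vapply(1:20, function(s) {
    tab <- generate_feature_table(synth_table_config(
      n_samples = 100L, d_informative = 2L, d_noise = 2L, effect_size = 0,
      seed = s))
    oracle_knn_cv(tab$values, tab$labels, k = 10L, folds = 5L, seed = s)
  }, 0)
  # Monte-Carlo tolerance: SE of the mean of 20 runs of ~Binomial(100, .5)
  expect_lt(abs(mean(accs) - 0.5), 0.05)
})
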