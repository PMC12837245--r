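test_that("squared Euclidean dissimilarity matches direct arithmetic", {
  expect_identical(squared_euclidean(c(0, 0), c(3, 4)), 25)
  expect_identical(squared_euclidean(c(1.5, -2, 7), c(1.5, -2, 7)), 0)
  expect_error(squared_euclidean(1:2, 1:3), "dimension")
})

test_that("Lloyd clustering solves the separable 1-D toy case exactly", {
  km <- bcghyper:::fit_kmeans(matrix(c(0, 0, 10, 10), 4, 1), K = 2L, seed = 1L)
  expect_equal(unname(sort(km$centers[, 1])), c(0, 10))
  expect_equal(km$inertia, 0)
  expect_equal(km$occupancy, c(0.5, 0.5))
  expect_error(bcghyper:::fit_kmeans(matrix(1:2, 2, 1), K = 3L), "fewer")
})

test_that("kmeans features have fixed length and are seed-deterministic", {
  segs <- small_segments(n_per_class = 2L, duration = 20, seed = 9L)
  f1 <- kmeans_features(segs, K = 3L, frame_seconds = 1, seed = 4L)
  f2 <- kmeans_features(segs, K = 3L, frame_seconds = 1, seed = 4L)
  expect_identical(f1, f2)
  expect_identical(ncol(f1$values), 3L * 4L + 3L + 1L)
  expect_identical(nrow(f1$values), 4L)
  expect_error(kmeans_features(segs, K = 30L, frame_seconds = 1), "fewer")
})

test_that("modwt yields full-length bands and conserves energy exactly", {
  set.seed(1)
  x <- rnorm(512)
  d <- modwt(x, "db4", 5L)
  expect_identical(dim(d$W), c(5L, 512L))
  expect_length(d$V, 512L)
  energy <- sum(d$W^2) + sum(d$V^2)
  expect_lt(abs(energy - sum(x^2)) / sum(x^2), 1e-6)
  expect_lt(sqrt(sum((imodwt(d) - x)^2) / sum(x^2)), 1e-8)
  # wavelets annihilate constants
  dc <- modwt(rep(3, 256), "db4", 4L)
  expect_lt(sum(dc$W^2) / sum(rep(3, 256)^2), 1e-8)
  expect_error(modwt(x, "sym9", 3L), "unsupported")
  expect_error(modwt(rnorm(16), "db4", 5L), "support")
})

test_that("modwt features summarize every band of every segment", {
  segs <- small_segments(n_per_class = 2L, duration = 20, seed = 10L)
  ft <- modwt_features(segs, "db4", 4L)
  expect_identical(dim(ft$values), c(4L, 5L * 5L))
  expect_false(any(!is.finite(ft$values)))
  expect_identical(ft$provenance$extractor, "modwt")
})

test_that("ewt places the two-tone boundary at the spectral midpoint", {
  t_grid <- (0:999) / 100
  tone <- sin(2 * pi * 5 * t_grid) + sin(2 * pi * 20 * t_grid)
  bd <- ewt_boundaries(tone, 100, 2L)
  expect_equal(bd$boundaries, 12.5)
  expect_equal(bd$peaks, c(5, 20))
  dec <- ewt_decompose(tone, 100, 2L)
  # each mode isolates one tone
  c1 <- spectral_centroid_oracle <- function(w) {
    p <- Mod(stats::fft(w))[1:501]^2
    sum((0:500) * 0.1 * p) / sum(p)
  }
  expect_lt(c1(dec$modes[1, ]), 10)
  expect_gt(c1(dec$modes[2, ]), 15)
})

test_that("ewt filter bank is a tight partition: modes sum back to the input", {
  set.seed(2)
  for (x in list(rnorm(300), sin(2 * pi * 3 * (0:299) / 100) + rnorm(300, 0, .1))) {
    dec <- ewt_decompose(x, 100, 5L)
    expect_lt(sqrt(sum((colSums(dec$modes) - x)^2) / sum(x^2)), 1e-3)
  }
  # single mode is the identity filter bank
  x <- rnorm(200)
  dec1 <- ewt_decompose(x, 100, 1L)
  expect_identical(nrow(dec1$modes), 1L)
  expect_lt(sqrt(sum((dec1$modes[1, ] - x)^2) / sum(x^2)), 1e-6)
})

test_that("ewt features are fixed-length even when modes fall back", {
  segs <- small_segments(n_per_class = 2L, duration = 20, seed = 11L)
  ft <- ewt_features(segs, 4L)
  expect_identical(dim(ft$values), c(4L, 16L))
  expect_false(any(!is.finite(ft$values)))
  # requesting more modes than spectral maxima degrades gracefully
  t_grid <- (0:499) / 100
  pure <- sin(2 * pi * 7 * t_grid)
  expect_warning(bd <- ewt_boundaries(pure, 100, 6L), "maxima")
  expect_lt(bd$n_modes, 6L)
})

test_that("linear-kernel kpca equals classical PCA up to component sign", {
  set.seed(3)
  X <- matrix(rnorm(40 * 6), 40, 6)
  m <- kpca_fit(X, "linear", 4L)
  pr <- prcomp(X, center = TRUE, scale. = FALSE)
  for (j in 1:4) {
    err <- min(max(abs(m$train_projections[, j] - pr$x[, j])),
               max(abs(m$train_projections[, j] + pr$x[, j])))
    expect_lt(err, 1e-8)
  }
  # training projections have variance equal to the eigenvalue
  expect_equal(unname(apply(m$train_projections, 2, var)), m$eigenvalues,
               tolerance = 1e-8)
  # transform of training rows reproduces the stored projections
  expect_equal(kpca_transform(m, X[1:7, ]), m$train_projections[1:7, ],
               tolerance = 1e-8)
})

test_that("kernel definitions and guards hold", {
  set.seed(4)
  X <- matrix(rnorm(20 * 3), 20, 3)
  K <- bcghyper:::kernel_matrix(X, X, "gaussian", list(bandwidth = 1.3))
  expect_equal(unname(diag(K)), rep(1, 20))           # K(p, p) = 1
  expect_identical(max(abs(K - t(K))), 0)             # symmetry
  expect_error(kpca_fit(X, "linear", 10L), "n_components")
  expect_error(bcghyper:::kernel_matrix(X, X, "wavelet", list()), "unsupported")
})

test_that("rfm mapping is non-negative; lasso fine-tune honors its limits", {
  set.seed(5)
  X <- scale(matrix(rnorm(60 * 5), 60, 5))
  model <- rfm_fit(X, q = 3L, n_per_group = 4L, gamma = 0.01, seed = 2L)
  Z <- rfm_transform(model, X)
  expect_true(all(Z >= 0))                            # ReLU range
  expect_identical(dim(Z), c(60L, 12L))
  expect_identical(rfm_fit(X, q = 3L, n_per_group = 4L, gamma = 0.01, seed = 2L),
                   model)
  # gamma = 0 reduces the fine-tune to least squares (normal-equations oracle)
  Zr <- bcghyper:::relu(X %*% matrix(rnorm(5 * 4), 5, 4) + 0.1)
  y <- rnorm(60)
  expect_lt(max(abs(bcghyper:::lasso_cd(Zr, y, 0) - qr.solve(Zr, y))), 1e-6)
  # very large gamma shrinks all fine-tuned weights to zero
  big <- rfm_fit(X, q = 2L, n_per_group = 3L, gamma = 1e7, seed = 3L)
  expect_true(all(vapply(big$groups, function(g) max(abs(g$W)), 0) == 0))
  expect_error(rfm_fit(X, gamma = -1), "gamma")
})

test_that("every extractor returns one fixed-length finite row per segment", {
  segs <- small_segments(n_per_class = 2L, duration = 20, seed = 12L)
  for (f in list(function(s) kmeans_features(s, K = 3L, frame_seconds = 1),
                 function(s) modwt_features(s, levels = 3L),
                 function(s) ewt_features(s, 3L))) {
    tab <- f(segs)
    expect_identical(nrow(tab$values), nrow(segs$segments))
    expect_false(any(!is.finite(tab$values)))
    expect_false(anyDuplicated(tab$feature_names) > 0)
  }
})
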