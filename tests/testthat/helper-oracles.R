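# Independent oracles and small fixture builders shared across tests.

# Direct Shannon entropy (bits) of a probability vector.
oracle_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Information gain computed directly from a discrete feature/label table,
# independent of the package's binning path.
oracle_ig <- function(f, y) {
  tab <- table(f, y)
  h_prior <- oracle_entropy(colSums(tab) / sum(tab))
  h_cond <- 0
  for (k in seq_len(nrow(tab))) {
    pk <- sum(tab[k, ]) / sum(tab)
    if (pk > 0) h_cond <- h_cond + pk * oracle_entropy(tab[k, ] / sum(tab[k, ]))
  }
  h_prior - h_cond
}

# Exhaustive minimum wrapper fitness over all non-empty masks of d features.
oracle_brute_force_fitness <- function(table, evaluator) {
  d <- ncol(table$values)
  masks <- as.matrix(expand.grid(rep(list(0:1), d)))[-1, , drop = FALSE]
  min(apply(masks, 1, selection_fitness, evaluator = evaluator))
}

# A small table where exactly one feature carries all the signal.
toy_d3_table <- function(seed = 11L, n = 40L) {
  generate_feature_table(synth_table_config(
    n_samples = n, d_informative = 1L, d_noise = 2L, effect_size = 3,
    seed = seed))
}

# Two-class Gaussian segments fixture: short synthetic cohort segments.
small_segments <- function(n_per_class = 6L, duration = 30, seed = 5L) {
  coh <- generate_bcg_cohort(synth_cohort_config(
    n_normal = n_per_class, n_hyper = n_per_class, duration = duration,
    seed = seed))
  segment_cohort(coh, duration)
}

# Direct 10-fold CV accuracy of a k-NN on a plain matrix (used as the
# Bayes-separability oracle for the synthetic table generator).
oracle_knn_cv <- function(X, y, k = 10L, folds = 10L, seed = 1L) {
  set.seed(seed)
  n <- nrow(X)
  idx <- split(sample(n), rep_len(seq_len(folds), n))
  accs <- vapply(idx, function(test) {
    train <- setdiff(seq_len(n), test)
    pred <- class::knn(X[train, , drop = FALSE], X[test, , drop = FALSE],
                       y[train], k = k)
    mean(pred == y[test])
  }, 0)
  mean(accs)
}
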