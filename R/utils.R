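# Internal helpers shared across modules: seeded evaluation that does not
# disturb the caller's RNG stream, seed derivation, and small checks.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so pipeline stages stay independently
# reproducible.
with_local_seed <- function(seed, code) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a base seed and an integer key; kept below 2^31 so
# it is always a valid set.seed() argument.
derive_seed <- function(seed, key) {
  as.integer(((as.numeric(seed) %% 2147483629) * 7919 + as.numeric(key)) %% 2147483629)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x, min = 1L) {
  length(x) == 1L && is.finite(x) && x >= min && x == round(x)
}

is_number <- function(x, min = -Inf) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= min
}

# Class labels used throughout: 0 = normal, 1 = hypertensive.
CLASS_LEVELS <- c("normal", "hypertensive")

as_class_factor <- function(x) {
  if (is.factor(x)) x <- as.character(x)
  if (is.numeric(x)) x <- CLASS_LEVELS[x + 1L]
  if (!all(x %in% CLASS_LEVELS)) {
    stopf("labels must be %s (or 0/1)", paste(CLASS_LEVELS, collapse = "/"))
  }
  factor(x, levels = CLASS_LEVELS)
}

# Weighted bootstrap resample of size n that is guaranteed to contain every
# class present in `y`; used by all boosting variants so that weak learners
# never see a single-class sample. Retries are part of the seeded stream.
weighted_resample <- function(n, prob, y, seed, max_tries = 25L) {
  with_local_seed(seed, {
    for (i in seq_len(max_tries)) {
      idx <- sample.int(n, n, replace = TRUE, prob = prob)
      if (length(unique(y[idx])) == length(unique(y))) return(idx)
    }
    # Fall back: force one sample from each class.
    idx <- sample.int(n, n, replace = TRUE, prob = prob)
    for (cl in unique(y)) {
      if (!any(y[idx] == cl)) idx[sample.int(n, 1L)] <- sample(which(y == cl), 1L)
    }
    idx
  })
}

# 10-NN (or k-NN) scorer with a deterministic tie-break: class::knn resolves
# ties at random, so every call runs under a seed derived from the inputs.
knn_predict <- function(train_x, test_x, train_y, k, seed) {
  k <- min(k, nrow(train_x))
  with_local_seed(seed, {
    class::knn(train = train_x, test = test_x, cl = train_y, k = k)
  })
}
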