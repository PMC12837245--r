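# Filter and wrapper feature selection: information gain, the shared Eq-style
# wrapper fitness (weighted error + feature-selection ratio), the V-shaped
# transfer function, and the construction of selection-mask results.

#' V-shaped transfer function
#'
#' `T.F(t) = (2/pi) * arctan((pi/2) * |t|)`: maps a continuous position update
#' to a bit-flip probability in `[0, 1)`. Applied elementwise.
#'
#' @param t numeric vector.
#' @return Probabilities in `[0, 1)`.
#' @export
vshape_transfer <- function(t) {
  (2 / pi) * atan((pi / 2) * abs(t))
}

entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

equal_freq_bins <- function(x, bins) {
  qs <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1),
                               names = FALSE, type = 7))
  if (length(qs) <= 2L) return(factor(rep(1L, length(x))))
  cut(x, breaks = c(-Inf, qs[-c(1, length(qs))], Inf), labels = FALSE) |> factor()
}

#' Information-gain feature scoring and selection
#'
#' Continuous features are discretized into `bins` equal-frequency bins; each
#' feature's information gain is the class entropy minus the class entropy
#' conditional on the binned feature (log base 2). The returned mask keeps
#' features whose gain exceeds the mean gain.
#'
#' @param table a [feature_table()] with both classes present.
#' @param bins number of equal-frequency bins.
#' @return A `selection_mask` with per-feature `scores` (bits).
#' @export
information_gain <- function(table, bins = 10L) {
  y <- table$labels
  if (length(unique(y)) < 2L) stopf("information gain needs >= 2 classes")
  h_prior <- entropy_bits(as.vector(table(y)) / length(y))
  scores <- apply(table$values, 2, function(x) {
    f <- equal_freq_bins(x, bins)
    tab <- table(f, y)
    pf <- rowSums(tab) / sum(tab)
    h_cond <- sum(vapply(seq_len(nrow(tab)), function(k) {
      if (pf[k] == 0) return(0)
      pf[k] * entropy_bits(tab[k, ] / sum(tab[k, ]))
    }, 0))
    h_prior - h_cond
  })
  mask <- as.integer(scores > mean(scores))
  if (sum(mask) == 0L) mask[which.max(scores)] <- 1L
  new_selection_mask(mask, fitness = NA_real_, selector = "ig",
                     scores = scores, params = list(bins = bins))
}

new_selection_mask <- function(mask, fitness, selector, scores = NULL,
                               params = list(), trace = NULL) {
  structure(list(mask = as.integer(mask), fsr = mean(mask != 0),
                 fitness = fitness, selector = selector, scores = scores,
                 params = params, trace = trace),
            class = "selection_mask")
}

#' @export
print.selection_mask <- function(x, ...) {
  cat(sprintf("<selection_mask> %s: %d/%d features (FSR %.3f), fitness %s\n",
              x$selector, sum(x$mask), length(x$mask), x$fsr,
              if (is.na(x$fitness)) "NA" else signif(x$fitness, 5)))
  invisible(x)
}

#' Serialize a selection mask as delimited text
#'
#' Columns: `feature_name, selected, score`.
#'
#' @param mask a `selection_mask`.
#' @param feature_names feature names matching the mask length.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_selection_mask <- function(mask, feature_names, path) {
  utils::write.csv(data.frame(feature_name = feature_names,
                              selected = mask$mask,
                              score = mask$scores %||% rep(NA_real_, length(mask$mask))),
                   path, row.names = FALSE)
  invisible(path)
}

#' Wrapper fitness evaluator
#'
#' The evaluator scores a candidate feature mask by
#' `k1 * error + k2 * FSR`, where the error is the mean misclassification
#' rate of a 10-nearest-neighbour classifier under stratified internal
#' cross-validation on the supplied (training-only) table, and FSR is the
#' fraction of features kept. Fold assignment is frozen at construction, and
#' evaluations are memoized per mask, so the fitness is a deterministic
#' function of the mask.
#'
#' @param table a [feature_table()]; pass only training rows to avoid leakage.
#' @param k1,k2 fitness weights in `[0, 1]` (defaults prioritize error).
#' @param internal_folds internal CV folds.
#' @param knn_k neighbour count of the internal scorer.
#' @param seed RNG seed for fold assignment and k-NN tie-breaking.
#' @return An object of class `fitness_evaluator`.
#' @export
fitness_evaluator <- function(table, k1 = 0.99, k2 = 0.01,
                              internal_folds = 3L, knn_k = 10L, seed = 1L) {
  stopifnot(k1 >= 0, k1 <= 1, k2 >= 0, k2 <= 1)
  folds <- stratified_folds(seq_len(nrow(table$values)), table$labels,
                            internal_folds, derive_seed(seed, 777L))
  structure(list(table = table, k1 = k1, k2 = k2,
                 internal_folds = internal_folds, knn_k = knn_k, seed = seed,
                 folds = folds, cache = new.env(parent = emptyenv()),
                 n_evals = new.env(parent = emptyenv())),
            class = "fitness_evaluator")
}

#' Evaluate the wrapper fitness of a feature mask
#'
#' Empty masks are repaired upstream by the selectors; here a mask selecting
#' no feature is an error.
#'
#' @param mask binary vector (length = number of features).
#' @param evaluator a [fitness_evaluator()].
#' @return The fitness value `k1 * error + k2 * FSR` (lower is better).
#' @export
selection_fitness <- function(mask, evaluator) {
  mask <- as.integer(mask != 0)
  if (sum(mask) == 0L) stopf("mask selects no features")
  key <- paste(mask, collapse = "")
  hit <- evaluator$cache[[key]]
  if (!is.null(hit)) return(hit)
  tab <- evaluator$table
  X <- tab$values[, mask == 1L, drop = FALSE]
  y <- tab$labels
  errs <- vapply(seq_along(evaluator$folds), function(fi) {
    test <- evaluator$folds[[fi]]
    train <- setdiff(seq_len(nrow(X)), test)
    pred <- knn_predict(X[train, , drop = FALSE], X[test, , drop = FALSE],
                        y[train], evaluator$knn_k,
                        derive_seed(evaluator$seed, 1000L + fi))
    mean(pred != y[test])
  }, 0)
  fit <- evaluator$k1 * mean(errs) + evaluator$k2 * mean(mask)
  evaluator$cache[[key]] <- fit
  fit
}

# Stratified fold assignment over arbitrary units (rows or subjects).
stratified_folds <- function(units, labels, k, seed) {
  with_local_seed(seed, {
    folds <- vector("list", k)
    for (cl in levels(factor(labels))) {
      u <- units[labels == cl]
      u <- u[sample.int(length(u))]
      for (i in seq_along(u)) {
        fi <- ((i - 1L) %% k) + 1L
        folds[[fi]] <- c(folds[[fi]], u[i])
      }
    }
    folds
  })
}

# Shared helpers for the binary metaheuristics -------------------------------

# The first agent always starts from the all-features mask, so with elitism
# the returned fitness can never exceed the all-features fitness.
random_population <- function(pop, d) {
  B <- matrix(stats::runif(pop * d) < 0.5, pop, d) * 1L
  B[1, ] <- 1L
  for (i in seq_len(pop)) if (sum(B[i, ]) == 0L) B[i, sample.int(d, 1L)] <- 1L
  B
}

repair_mask <- function(bits) {
  if (sum(bits) == 0L) bits[sample.int(length(bits), 1L)] <- 1L
  bits
}

# Binarization shared by BTSA/AOA/BPSO: each bit is complemented with
# probability T.F(continuous update), else retained.
flip_binarize <- function(bits, continuous) {
  p <- vshape_transfer(continuous)
  flip <- stats::runif(length(bits)) < p
  bits[flip] <- 1L - bits[flip]
  repair_mask(bits)
}

evaluate_population <- function(B, evaluator) {
  apply(B, 1, selection_fitness, evaluator = evaluator)
}

finish_wrapper <- function(best_bits, best_fit, selector, params, trace) {
  new_selection_mask(best_bits, fitness = best_fit, selector = selector,
                     params = params, trace = trace)
}

#' Binary tunicate swarm feature selection
#'
#' Continuous jet-propulsion/swarm dynamics (gravity, social force and
#' water-flow advection; distance-to-best attraction; averaging position
#' update) drive a population of agents; positions are binarized with the
#' V-shaped transfer flip rule, and an elitist global best is tracked.
#' Defaults (`pop = 100`, `generations = 1000`) match the reference settings;
#' use smaller values for interactive work.
#'
#' @param table a [feature_table()] of training rows.
#' @param evaluator a [fitness_evaluator()]; built from `table` if `NULL`.
#' @param pop population size (>= 2).
#' @param generations number of generations.
#' @param seed RNG seed (bit-reproducible runs).
#' @param w_min,w_max minimum/maximum tunicate speeds of the social-force
#'   term.
#' @return A `selection_mask` with a `trace` of best fitness per generation.
#' @export
btsa_select <- function(table, evaluator = NULL, pop = 100L,
                        generations = 1000L, seed = 1L, w_min = 1,
                        w_max = 20) {
  if (!is_count(pop, 2L)) stopf("pop must be >= 2")
  if (is.null(evaluator)) evaluator <- fitness_evaluator(table, seed = seed)
  d <- ncol(table$values)
  with_local_seed(derive_seed(seed, 42L), {
    B <- random_population(pop, d)
    C <- matrix(stats::runif(pop * d, -1, 1), pop, d)
    fits <- evaluate_population(B, evaluator)
    best_i <- which.min(fits)
    best_fit <- fits[best_i]
    best_bits <- B[best_i, ]
    best_cont <- C[best_i, ]
    trace <- numeric(generations)
    for (g in seq_len(generations)) {
      for (h in seq_len(pop)) {
        k1 <- stats::runif(1); k2 <- stats::runif(1); k3 <- stats::runif(1)
        G <- k1 + k2 - 2 * k3                 # gravity minus water-flow advection
        S <- w_min + k3 * (w_max - w_min)     # social force
        Tf <- G / S
        r1 <- stats::runif(1)
        D <- abs(best_cont - r1 * C[h, ])
        newpos <- if (stats::runif(1) >= 0.5) best_cont + Tf * D else best_cont - Tf * D
        C[h, ] <- pmin(pmax((newpos + best_cont) / (2 + k1), -6), 6)
        B[h, ] <- flip_binarize(B[h, ], C[h, ])
        f <- selection_fitness(B[h, ], evaluator)
        if (f < best_fit) {
          best_fit <- f
          best_bits <- B[h, ]
          best_cont <- C[h, ]
        }
      }
      trace[g] <- best_fit
    }
    finish_wrapper(best_bits, best_fit, "btsa",
                   list(pop = pop, generations = generations, seed = seed,
                        w_min = w_min, w_max = w_max), trace)
  })
}

#' Levy-flight scale parameter
#'
#' `sigma(alpha) = Gamma(1 + alpha) sin(pi alpha / 2) /
#'  (Gamma((1 + alpha) / 2) * alpha * 2^((alpha - 1) / 2))`.
#'
#' @param alpha stability constant (default 0.5).
#' @return The positive scale `sigma`.
#' @export
levy_sigma <- function(alpha = 0.5) {
  gamma(1 + alpha) * sin(pi * alpha / 2) /
    (gamma((1 + alpha) / 2) * alpha * 2^((alpha - 1) / 2))
}

# Levy step vector: c * u * sigma / |v|^(1/beta); u, v standard normal.
levy_step <- function(d, c = 0.1, alpha = 0.5, beta = 1.5) {
  u <- stats::rnorm(d)
  v <- stats::rnorm(d)
  c * u * levy_sigma(alpha) / abs(v)^(1 / beta)
}

#' Aquila optimizer feature selection
#'
#' Four hunting-strategy position updates: expanded exploration (toward the
#' best and the population mean) and focused exploration (Levy flight around a
#' random agent with a spiral term) during the first two-thirds of the
#' iterations; expanded exploitation (`lambda = sigma = 0.5`) and forwarded
#' exploitation (quality-factor weighted with Levy steps) afterwards, choosing
#' within each pair with probability one half. Continuous positions live in
#' `[lb, ub]` and are binarized with the V-shaped transfer flip rule; an
#' elitist global best is tracked.
#'
#' @inheritParams btsa_select
#' @param lb,ub continuous position bounds.
#' @return A `selection_mask` with a `trace` of best fitness per generation.
#' @export
aoa_select <- function(table, evaluator = NULL, pop = 100L,
                       generations = 1000L, seed = 1L, lb = 0, ub = 1) {
  if (!is_count(pop, 2L)) stopf("pop must be >= 2")
  if (is.null(evaluator)) evaluator <- fitness_evaluator(table, seed = seed)
  d <- ncol(table$values)
  U_spiral <- 0.00565
  w_spiral <- 0.01
  theta1 <- 3 * pi / 2
  D1 <- rep_len(1:10, d)
  with_local_seed(derive_seed(seed, 43L), {
    B <- random_population(pop, d)
    Y <- matrix(stats::runif(pop * d, lb, ub), pop, d)
    fits <- evaluate_population(B, evaluator)
    best_i <- which.min(fits)
    best_fit <- fits[best_i]
    best_bits <- B[best_i, ]
    best_cont <- Y[best_i, ]
    trace <- numeric(generations)
    for (t in seq_len(generations)) {
      Yp <- colMeans(Y)
      for (h in seq_len(pop)) {
        r <- stats::runif(1)
        if (t <= 2 * generations / 3) {
          if (stats::runif(1) < 0.5) {
            ynew <- best_cont * (1 - t / generations) + (Yp - best_cont) * r
          } else {
            yr <- Y[sample.int(pop, 1L), ]
            r1 <- stats::runif(1, 1, 10)
            rs <- r1 * U_spiral * D1
            theta <- -w_spiral * D1 + theta1
            z <- rs * cos(theta)
            y_sp <- rs * sin(theta)
            ynew <- best_cont * levy_step(d) + yr + (z - y_sp) * r
          }
        } else {
          if (stats::runif(1) < 0.5) {
            rv <- stats::runif(d)
            ynew <- 0.5 * (best_cont - Yp) + 0.5 * ((ub - lb) * rv + lb)
          } else {
            G1 <- 2 * stats::runif(1) - 1
            G2 <- 2 * (1 - t / generations)
            QF <- t^((2 * stats::runif(1) - 1) / (1 - generations)^2)
            ynew <- QF * best_cont - G1 * Y[h, ] * r - G2 * levy_step(d) + r * G1
          }
        }
        Y[h, ] <- pmin(pmax(ynew, lb), ub)
        B[h, ] <- flip_binarize(B[h, ], Y[h, ])
        f <- selection_fitness(B[h, ], evaluator)
        if (f < best_fit) {
          best_fit <- f
          best_bits <- B[h, ]
          best_cont <- Y[h, ]
        }
      }
      trace[t] <- best_fit
    }
    finish_wrapper(best_bits, best_fit, "aoa",
                   list(pop = pop, generations = generations, seed = seed,
                        lb = lb, ub = ub), trace)
  })
}

#' Baseline feature selectors
#'
#' Filter baselines: `chi2` (chi-square statistic of the equal-frequency
#' binned feature against the label) and `pcc` (absolute point-biserial
#' correlation with the label), both keeping above-mean scorers. Wrapper
#' baselines: `bpso` (binary particle swarm) and `baco` (binary ant colony),
#' both driven by the same wrapper fitness and elitism as the main
#' metaheuristics.
#'
#' @param table a [feature_table()] of training rows.
#' @param method one of `"chi2"`, `"pcc"`, `"bpso"`, `"baco"`.
#' @param evaluator a [fitness_evaluator()] for the wrapper methods.
#' @param pop,generations,seed wrapper-search controls.
#' @param bins bins for the chi-square discretization.
#' @return A `selection_mask`.
#' @export
baseline_select <- function(table, method = c("chi2", "pcc", "bpso", "baco"),
                            evaluator = NULL, pop = 20L, generations = 50L,
                            seed = 1L, bins = 10L) {
  method <- match.arg(method)
  y <- table$labels
  switch(method,
    chi2 = {
      scores <- apply(table$values, 2, function(x) {
        f <- equal_freq_bins(x, bins)
        if (nlevels(f) < 2L) return(0)
        suppressWarnings(unname(stats::chisq.test(table(f, y))$statistic))
      })
      mask <- as.integer(scores > mean(scores))
      if (sum(mask) == 0L) mask[which.max(scores)] <- 1L
      new_selection_mask(mask, NA_real_, "chi2", scores, list(bins = bins))
    },
    pcc = {
      y01 <- as.integer(y == "hypertensive")
      scores <- apply(table$values, 2, function(x) {
        if (stats::sd(x) == 0) return(0)
        abs(stats::cor(x, y01))
      })
      mask <- as.integer(scores > mean(scores))
      if (sum(mask) == 0L) mask[which.max(scores)] <- 1L
      new_selection_mask(mask, NA_real_, "pcc", scores, list())
    },
    bpso = bpso_select(table, evaluator, pop, generations, seed),
    baco = baco_select(table, evaluator, pop, generations, seed))
}

bpso_select <- function(table, evaluator, pop, generations, seed,
                        inertia = 0.7, c1 = 1.5, c2 = 1.5, vmax = 6) {
  if (is.null(evaluator)) evaluator <- fitness_evaluator(table, seed = seed)
  d <- ncol(table$values)
  with_local_seed(derive_seed(seed, 44L), {
    B <- random_population(pop, d)
    V <- matrix(stats::runif(pop * d, -1, 1), pop, d)
    fits <- evaluate_population(B, evaluator)
    pbest <- B
    pbest_fit <- fits
    gi <- which.min(fits)
    best_bits <- B[gi, ]
    best_fit <- fits[gi]
    trace <- numeric(generations)
    for (g in seq_len(generations)) {
      for (h in seq_len(pop)) {
        r1 <- stats::runif(d); r2 <- stats::runif(d)
        V[h, ] <- pmin(pmax(inertia * V[h, ] + c1 * r1 * (pbest[h, ] - B[h, ]) +
                              c2 * r2 * (best_bits - B[h, ]), -vmax), vmax)
        B[h, ] <- flip_binarize(B[h, ], V[h, ])
        f <- selection_fitness(B[h, ], evaluator)
        if (f < pbest_fit[h]) {
          pbest_fit[h] <- f
          pbest[h, ] <- B[h, ]
        }
        if (f < best_fit) {
          best_fit <- f
          best_bits <- B[h, ]
        }
      }
      trace[g] <- best_fit
    }
    finish_wrapper(best_bits, best_fit, "bpso",
                   list(pop = pop, generations = generations, seed = seed), trace)
  })
}

baco_select <- function(table, evaluator, pop, generations, seed,
                        rho = 0.1, tau_min = 0.05, tau_max = 0.95) {
  if (is.null(evaluator)) evaluator <- fitness_evaluator(table, seed = seed)
  d <- ncol(table$values)
  with_local_seed(derive_seed(seed, 45L), {
    tau <- rep(0.5, d)
    best_bits <- rep(1L, d)
    best_fit <- selection_fitness(best_bits, evaluator)
    trace <- numeric(generations)
    for (g in seq_len(generations)) {
      gen_best_bits <- NULL
      gen_best_fit <- Inf
      for (a in seq_len(pop)) {
        bits <- repair_mask(as.integer(stats::runif(d) < tau))
        f <- selection_fitness(bits, evaluator)
        if (f < gen_best_fit) {
          gen_best_fit <- f
          gen_best_bits <- bits
        }
        if (f < best_fit) {
          best_fit <- f
          best_bits <- bits
        }
      }
      tau <- pmin(pmax((1 - rho) * tau + rho * gen_best_bits, tau_min), tau_max)
      trace[g] <- best_fit
    }
    finish_wrapper(best_bits, best_fit, "baco",
                   list(pop = pop, generations = generations, seed = seed), trace)
  })
}
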