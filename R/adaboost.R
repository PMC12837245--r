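# Discrete AdaBoost over an arbitrary weak-learner factory. Weak learners are
# trained on weight-proportional bootstrap resamples (so they need no
# weighted-fit capability); the weighted error, voting weights and
# distribution updates follow the classical scheme: eps_t measured on the
# full weighted training set, alpha_t = 0.5 log((1 - eps)/eps), weights
# multiplied by exp(-alpha y h) and renormalized.

#' Fit a boosted ensemble of weak learners
#'
#' @param table a [feature_table()] with two classes.
#' @param base_fit function `(X, y, seed)` returning a fitted weak learner;
#'   `y` is a factor with the table's class levels.
#' @param base_predict function `(model, X)` returning a factor of class
#'   predictions.
#' @param T number of boosting rounds (>= 1).
#' @param seed RNG seed; round `t` uses the derived seed `seed + t` for its
#'   resample.
#' @param eps_clip lower clip for zero weighted error.
#' @return An object of class `boost_ensemble`: `models`, `alphas`,
#'   `epsilons`, per-round sample-weight history and the class levels.
#' @export
adaboost_fit <- function(table, base_fit, base_predict, T = 50L, seed = 1L,
                         eps_clip = 1e-10) {
  if (!is_count(T)) stopf("T must be a count >= 1")
  X <- table$values
  y <- droplevels(table$labels)
  if (nlevels(y) != 2L) stopf("adaboost needs exactly two classes")
  n <- nrow(X)
  ysign <- ifelse(y == levels(y)[2L], 1, -1)      # positive class = second level
  D <- rep(1 / n, n)
  models <- list()
  alphas <- numeric()
  epsilons <- numeric()
  Dhist <- list()
  for (t in seq_len(T)) {
    idx <- weighted_resample(n, D, y, derive_seed(seed, t))
    model <- base_fit(X[idx, , drop = FALSE], y[idx], derive_seed(seed, 10000L + t))
    pred <- base_predict(model, X)
    hsign <- ifelse(pred == levels(y)[2L], 1, -1)
    mis <- hsign != ysign
    eps <- sum(D[mis])
    if (eps >= 0.5) {
      if (t == 1L) {
        warnf("adaboost: first weak learner no better than chance (eps = %.3f); ensemble of 1", eps)
        eps <- min(eps, 0.5 - 1e-6)
        alpha <- 0.5 * log((1 - eps) / eps)
        models[[1]] <- model
        alphas <- alpha
        epsilons <- eps
        Dhist[[1]] <- D
      }
      break
    }
    stopped <- eps <= 0
    eps <- max(eps, eps_clip)
    alpha <- 0.5 * log((1 - eps) / eps)
    models[[t]] <- model
    alphas <- c(alphas, alpha)
    epsilons <- c(epsilons, eps)
    D <- D * exp(-alpha * ysign * hsign)
    D <- D / sum(D)
    Dhist[[t]] <- D
    if (stopped) break
  }
  structure(list(models = models, alphas = alphas, epsilons = epsilons,
                 weight_history = Dhist, levels = levels(y),
                 base_predict = base_predict, T = length(models), seed = seed),
            class = "boost_ensemble")
}

#' Predict with a boosted ensemble
#'
#' Weighted vote `H(a) = sign(sum alpha_t h_t(a))`; a zero score resolves to
#' the first (lower-index) class.
#'
#' @param object a `boost_ensemble`.
#' @param newdata a [feature_table()] or numeric matrix.
#' @param type `"class"` or `"score"` (the signed weighted sum).
#' @param ... unused.
#' @export
predict.boost_ensemble <- function(object, newdata, type = c("class", "score"),
                                   ...) {
  type <- match.arg(type)
  X <- if (inherits(newdata, "feature_table")) newdata$values else as.matrix(newdata)
  score <- numeric(nrow(X))
  for (t in seq_along(object$models)) {
    pred <- object$base_predict(object$models[[t]], X)
    hsign <- ifelse(pred == object$levels[2L], 1, -1)
    score <- score + object$alphas[t] * hsign
  }
  if (type == "score") return(score)
  factor(ifelse(score > 0, object$levels[2L], object$levels[1L]),
         levels = object$levels)
}

#' @export
print.boost_ensemble <- function(x, ...) {
  cat(sprintf("<boost_ensemble> %d round(s); alphas in [%.3g, %.3g]\n",
              x$T, min(x$alphas), max(x$alphas)))
  invisible(x)
}

#' Classical boosting bound on the training error
#'
#' `prod_t 2 sqrt(eps_t (1 - eps_t))`: the final ensemble's training error is
#' guaranteed not to exceed this product.
#'
#' @param ensemble a `boost_ensemble`.
#' @return The bound (a number in `[0, 1]`).
#' @export
boosting_bound <- function(ensemble) {
  prod(2 * sqrt(ensemble$epsilons * (1 - ensemble$epsilons)))
}

#' Hybrid AdaBoost-MULDA classifier
#'
#' Boosting with a MULDA-projection + k-nearest-neighbour base learner
#' trained on weight-proportional resamples: misclassified samples gain
#' weight, so successive MULDA learners concentrate on the error-prone
#' region.
#'
#' @param table a [feature_table()].
#' @param T boosting rounds.
#' @param knn_k neighbour count of the MULDA scorer.
#' @param seed RNG seed.
#' @return A `boost_ensemble`.
#' @export
hybrid_adaboost_mulda <- function(table, T = 20L, knn_k = 10L, seed = 1L) {
  lv <- levels(droplevels(table$labels))
  base_fit <- function(X, y, s) {
    mulda_fit(feature_table(X, factor(y, levels = CLASS_LEVELS)),
              knn_k = knn_k, seed = s)
  }
  base_predict <- function(model, X) predict(model, X)
  adaboost_fit(table, base_fit, base_predict, T = T, seed = seed)
}

#' Hybrid AdaBoost-random-forest classifier
#'
#' Boosting with a small depth-limited random forest as the weak learner;
#' the distribution update is the classical AdaBoost one.
#'
#' @param table a [feature_table()].
#' @param T boosting rounds.
#' @param n_trees trees per weak forest.
#' @param max_nodes terminal-node cap per tree (depth limit).
#' @param seed RNG seed.
#' @return A `boost_ensemble`.
#' @export
hybrid_adaboost_rf <- function(table, T = 20L, n_trees = 20L, max_nodes = 8L,
                               seed = 1L) {
  if (nrow(table$values) < 2L) stopf("need at least two samples")
  if (all(apply(table$values, 2, stats::sd) == 0)) {
    stopf("degenerate table: every feature is constant")
  }
  base_fit <- function(X, y, s) {
    with_local_seed(s, randomForest::randomForest(
      x = X, y = droplevels(y), ntree = n_trees, maxnodes = max_nodes))
  }
  # tree-vote ties are broken by the RNG; seed them for determinism
  base_predict <- function(model, X) {
    with_local_seed(derive_seed(seed, 31L), predict(model, X))
  }
  adaboost_fit(table, base_fit, base_predict, T = T, seed = seed)
}
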