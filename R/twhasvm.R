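# Time-weighted hybrid AdaBoost-SVM: boosted polynomial-kernel SVMs whose
# initial sample weights carry an exponential batch-age decay exp(-eta * t).
# With eta = 0 or batch 1 the decay is a no-op and the model coincides with a
# plain AdaBoost of SVMs built with the same seeds.

#' Batch time-weight
#'
#' `TW(t) = exp(-eta * t)` for batch age `t = 0, 1, ...`; `TW(0) = 1`.
#'
#' @param t batch age (batch_index - 1).
#' @param eta decay rate in `[0, 0.5]`.
#' @return The multiplicative weight.
#' @export
time_weight <- function(t, eta) {
  if (eta < 0 || eta > 0.5) stopf("eta must lie in [0, 0.5]")
  exp(-eta * t)
}

#' Fit a time-weighted hybrid AdaBoost-SVM classifier
#'
#' Initial per-sample weights `1/n` are multiplied by the batch time-weight
#' `TW(batch_index - 1)` and renormalized. Each round normalizes the weights,
#' trains a polynomial-kernel SVM on a weight-proportional resample, measures
#' the weighted error on the full set, assigns the voting weight
#' `alpha_t = 0.5 log((1 - e_t)/e_t)` and multiplies misclassified samples'
#' weights by `exp(alpha_t)`. A zero error is clipped to `1e-10`; an error of
#' 0.5 or more stops the round loop, keeping the rounds so far.
#'
#' @param table a [feature_table()].
#' @param eta time-decay rate in `[0, 0.5]`.
#' @param batch_index current data-batch number (1 = no decay).
#' @param T boosting rounds.
#' @param poly_degree polynomial kernel degree.
#' @param cost SVM regularization constant.
#' @param seed RNG seed; round `t` resamples under the derived seed
#'   `seed + t`.
#' @return An object of class `tw_hasvm_model` with learners `C_t` and voting
#'   weights `alpha_t`.
#' @export
tw_hasvm_fit <- function(table, eta = 0, batch_index = 1L, T = 20L,
                         poly_degree = 3L, cost = 1, seed = 1L) {
  if (!is_count(T)) stopf("T must be a count >= 1")
  if (!is_count(batch_index)) stopf("batch_index must be a count >= 1")
  X <- table$values
  y <- droplevels(table$labels)
  n <- nrow(X)
  w <- rep(1 / n, n) * time_weight(batch_index - 1L, eta)
  w <- w / sum(w)
  learners <- list()
  alphas <- numeric()
  errors <- numeric()
  for (t in seq_len(T)) {
    w <- w / sum(w)                               # N_t normalization
    idx <- weighted_resample(n, w, y, derive_seed(seed, t))
    Ct <- e1071::svm(x = X[idx, , drop = FALSE], y = y[idx],
                     kernel = "polynomial", degree = poly_degree, cost = cost,
                     scale = FALSE)
    pred <- predict(Ct, X)
    mis <- pred != y
    e <- sum(w[mis])
    if (e >= 0.5) {
      if (length(learners) == 0L) {
        warnf("tw-hasvm: first weak SVM no better than chance (e = %.3f); keeping it", e)
        e <- min(e, 0.5 - 1e-6)
      } else break
    }
    e <- max(e, 1e-10)
    alpha <- 0.5 * log((1 - e) / e)
    learners[[length(learners) + 1L]] <- Ct
    alphas <- c(alphas, alpha)
    errors <- c(errors, e)
    w <- w * exp(alpha * mis)
    if (e <= 1e-10) break
  }
  structure(list(learners = learners, alphas = alphas, errors = errors,
                 eta = eta, batch_index = batch_index, levels = levels(y),
                 poly_degree = poly_degree, seed = seed),
            class = "tw_hasvm_model")
}

#' Predict with a TW-HASVM model
#'
#' Per-class weighted sums `S_cl(a) = sum_t alpha_t I[h_t(a) = cl]` decide
#' the label by argmax; ties break toward the lower class index.
#'
#' @param object a `tw_hasvm_model`.
#' @param newdata a [feature_table()] or numeric matrix.
#' @param ... unused.
#' @return A factor of predicted labels.
#' @export
predict.tw_hasvm_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "feature_table")) newdata$values else as.matrix(newdata)
  S <- matrix(0, nrow(X), length(object$levels),
              dimnames = list(NULL, object$levels))
  for (t in seq_along(object$learners)) {
    pred <- predict(object$learners[[t]], X)
    for (cl in object$levels) {
      S[, cl] <- S[, cl] + object$alphas[t] * (pred == cl)
    }
  }
  factor(object$levels[apply(S, 1, which.max)], levels = object$levels)
}

#' @export
print.tw_hasvm_model <- function(x, ...) {
  cat(sprintf("<tw_hasvm_model> %d SVM learner(s), eta = %g, batch %d, degree %d\n",
              length(x$learners), x$eta, x$batch_index, x$poly_degree))
  invisible(x)
}
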