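# ARIMA descriptor extraction per segment and the hybrid ARIMA-AdaBoost
# classifier: selected features are augmented with per-segment ARIMA
# coefficients and boosted with an AdaBoost.R2-style regression scheme on
# depth-1 regression trees.

# Augmented Dickey-Fuller-style unit-root screen: regress the first
# difference on the lagged level and lagged differences; a t-statistic below
# the 5% critical value (about -2.86 with constant) rejects a unit root.
adf_statistic <- function(x, lags = 4L) {
  dx <- diff(x)
  n <- length(dx)
  if (n <= lags + 2L) return(NA_real_)
  y <- dx[(lags + 1L):n]
  lag_level <- x[(lags + 1L):(length(x) - 1L)]
  Z <- cbind(1, lag_level)
  for (l in seq_len(lags)) Z <- cbind(Z, dx[(lags + 1L - l):(n - l)])
  fit <- stats::lm.fit(Z, y)
  res <- fit$residuals
  s2 <- sum(res^2) / (length(y) - ncol(Z))
  XtXinv <- tryCatch(solve(crossprod(Z)), error = function(e) NULL)
  if (is.null(XtXinv)) return(NA_real_)
  fit$coefficients[2] / sqrt(s2 * XtXinv[2, 2])
}

#' ARIMA coefficient features for one series
#'
#' The series is differenced `d` times; a unit-root screen on the differenced
#' series may add one further difference if nonstationarity is still
#' indicated. AR and MA coefficients are then fitted by conditional least
#' squares, and the coefficient vector, mean and residual variance are
#' returned as a fixed-length feature vector. A non-convergent fit falls back
#' to an AR-only fit with a warning.
#'
#' @param x numeric series (length well above `k + l`).
#' @param orders integer vector `(k, d, l)`: AR order, differencing degree,
#'   MA order.
#' @param adf_critical critical value of the unit-root screen.
#' @return An object of class `arima_spec`: `features` (named numeric of
#'   length `k + l + 2`), `orders` as used, `adf` statistic, `fallback` flag.
#' @export
arima_features <- function(x, orders = c(2L, 1L, 2L), adf_critical = -2.86) {
  k <- orders[1]; d <- orders[2]; l <- orders[3]
  if (any(orders < 0)) stopf("ARIMA orders must be >= 0")
  z <- x
  if (d > 0) for (i in seq_len(d)) z <- diff(z)
  if (length(z) < 20L + k + l) stopf("series too short after differencing")
  adf <- adf_statistic(z)
  if (!is.na(adf) && adf > adf_critical) {
    z <- diff(z)
    d <- d + 1L
  }
  fallback <- FALSE
  fit <- tryCatch(
    stats::arima(z, order = c(k, 0L, l), method = "CSS", include.mean = TRUE),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(fit)) {
    fallback <- TRUE
    warnf("arima_features: ARMA fit failed; falling back to AR-only fit")
    fit <- stats::arima(z, order = c(k, 0L, 0L), method = "CSS",
                        include.mean = TRUE)
  }
  co <- stats::coef(fit)
  phi <- numeric(k); theta <- numeric(l)
  ar_idx <- grep("^ar", names(co))
  ma_idx <- grep("^ma", names(co))
  phi[seq_along(ar_idx)] <- co[ar_idx]
  theta[seq_along(ma_idx)] <- co[ma_idx]
  mu <- if ("intercept" %in% names(co)) co[["intercept"]] else 0
  feats <- c(phi, theta, mu, fit$sigma2)
  names(feats) <- c(if (k) paste0("phi", seq_len(k)),
                    if (l) paste0("theta", seq_len(l)), "mu", "sigma2")
  structure(list(features = feats, orders = c(k, d, l), adf = adf,
                 fallback = fallback),
            class = "arima_spec")
}

# ARIMA descriptor matrix for all segments (unsupervised, so it can be
# computed once and shared across CV folds and permutations).
arima_descriptors <- function(segments, orders = c(2L, 1L, 2L)) {
  t(apply(segments$segments, 1, function(x) {
    suppressWarnings(arima_features(x, orders)$features)
  }))
}

#' Hybrid ARIMA-AdaBoost classifier
#'
#' Stage 1 augments each sample's selected features with its per-segment
#' ARIMA coefficient descriptors. Stage 2 boosts depth-1 regression trees on
#' the 0/1 class target with an AdaBoost.R2-style scheme: per-sample absolute
#' errors scaled to `[0, 1]`, proportional error
#' `eps_t = sum D_t(i) e_t(i)`, `beta_t = eps_t / (1 - eps_t)`, voting weight
#' `w_t = 0.5 log(1 / beta_t)`, and distribution update
#' `D ~ D * beta_t^(1 - e_i)`. The aggregate regressor is the weighted mean
#' of the weak regressors; class 1 (hypertensive) is predicted when it
#' reaches 0.5.
#'
#' @param table a [feature_table()] of selected features.
#' @param segments the matching `segment_set` (same row order), or `NULL` to
#'   skip the ARIMA augmentation.
#' @param T boosting rounds.
#' @param orders ARIMA orders `(k, d, l)`.
#' @param seed RNG seed.
#' @param arima_feats optional precomputed [arima_descriptors()] matrix.
#' @return An object of class `arima_adaboost_model`.
#' @export
hybrid_arima_adaboost <- function(table, segments = NULL, T = 20L,
                                  orders = c(2L, 1L, 2L), seed = 1L,
                                  arima_feats = NULL) {
  if (is.null(arima_feats) && !is.null(segments)) {
    arima_feats <- arima_descriptors(segments, orders)
  }
  X <- table$values
  if (!is.null(arima_feats)) X <- cbind(X, arima_feats)
  y <- as.integer(droplevels(table$labels) == "hypertensive")
  n <- nrow(X)
  D <- rep(1 / n, n)
  models <- list()
  wts <- numeric()
  epsilons <- numeric()
  df_all <- as.data.frame(X)
  names(df_all) <- paste0("x", seq_len(ncol(X)))
  for (t in seq_len(T)) {
    idx <- weighted_resample(n, D, y, derive_seed(seed, t))
    df <- df_all[idx, , drop = FALSE]
    df$.y <- y[idx]
    tree <- with_local_seed(derive_seed(seed, 10000L + t),
      rpart::rpart(.y ~ ., data = df, method = "anova",
                   control = rpart::rpart.control(maxdepth = 1L, minsplit = 2L,
                                                  cp = 0, xval = 0L)))
    f <- stats::predict(tree, df_all)
    e <- abs(f - y)
    emax <- max(e)
    perfect <- emax < 1e-12
    if (!perfect) e <- e / emax else e[] <- 0
    eps <- sum(D * e)
    if (eps >= 0.5) break
    eps <- max(eps, 1e-10)
    beta <- eps / (1 - eps)
    w <- 0.5 * log(1 / beta)
    models[[length(models) + 1L]] <- tree
    wts <- c(wts, w)
    epsilons <- c(epsilons, eps)
    D <- D * beta^(1 - e)
    D <- D / sum(D)
    if (perfect) break
  }
  if (length(models) == 0L) {
    # First round already at chance: keep it anyway so predictions exist.
    warnf("arima-adaboost: first weak regressor no better than chance; ensemble of 1")
    models <- list(tree)
    wts <- 1
    epsilons <- eps
  }
  structure(list(models = models, weights = wts, epsilons = epsilons,
                 orders = orders, uses_arima = !is.null(arima_feats),
                 n_features = ncol(table$values), seed = seed),
            class = "arima_adaboost_model")
}

#' @export
predict.arima_adaboost_model <- function(object, newdata, segments = NULL,
                                         arima_feats = NULL,
                                         type = c("class", "score"), ...) {
  type <- match.arg(type)
  X <- if (inherits(newdata, "feature_table")) newdata$values else as.matrix(newdata)
  if (object$uses_arima) {
    if (is.null(arima_feats)) {
      if (is.null(segments)) stopf("model was fitted with ARIMA augmentation; supply segments or arima_feats")
      arima_feats <- arima_descriptors(segments, object$orders)
    }
    X <- cbind(X, arima_feats)
  }
  df <- as.data.frame(X)
  names(df) <- paste0("x", seq_len(ncol(X)))
  F_ <- numeric(nrow(X))
  for (t in seq_along(object$models)) {
    F_ <- F_ + object$weights[t] * stats::predict(object$models[[t]], df)
  }
  F_ <- F_ / sum(object$weights)
  if (type == "score") return(F_)
  factor(ifelse(F_ >= 0.5, "hypertensive", "normal"), levels = CLASS_LEVELS)
}

#' @export
print.arima_adaboost_model <- function(x, ...) {
  cat(sprintf("<arima_adaboost_model> %d round(s), ARIMA orders (%s), arima features: %s\n",
              length(x$models), paste(x$orders, collapse = ","),
              if (x$uses_arima) "yes" else "no"))
  invisible(x)
}
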