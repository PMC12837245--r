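# Conventional comparison classifiers with fixed seeds, for the comparison
# columns of the results grid.

#' Baseline classifiers
#'
#' Fits one of the standard comparison classifiers: random forest (`rf`),
#' decision tree (`dt`), Gaussian naive Bayes (`nbc`) or standard AdaBoost on
#' decision stumps (`adaboost`).
#'
#' @param table a [feature_table()] with at least two samples and two
#'   classes.
#' @param method one of `"rf"`, `"dt"`, `"nbc"`, `"adaboost"`.
#' @param T boosting rounds for `adaboost`.
#' @param n_trees trees for `rf`.
#' @param seed RNG seed.
#' @return A classed model with a `predict` method returning factor labels.
#' @export
baseline_classifier <- function(table, method = c("rf", "dt", "nbc", "adaboost"),
                                T = 20L, n_trees = 100L, seed = 1L) {
  method <- match.arg(method)
  X <- table$values
  y <- droplevels(table$labels)
  if (nrow(X) < 2L) stopf("need at least two samples")
  if (nlevels(y) < 2L) stopf("need both classes present")
  model <- switch(method,
    rf = with_local_seed(seed, randomForest::randomForest(x = X, y = y,
                                                          ntree = n_trees)),
    dt = {
      df <- as.data.frame(X)
      names(df) <- paste0("x", seq_len(ncol(X)))
      df$.y <- y
      with_local_seed(seed, rpart::rpart(.y ~ ., data = df, method = "class",
                                         control = rpart::rpart.control(xval = 0L)))
    },
    nbc = e1071::naiveBayes(x = as.data.frame(X), y = y),
    adaboost = {
      base_fit <- function(Xr, yr, s) {
        df <- as.data.frame(Xr)
        names(df) <- paste0("x", seq_len(ncol(Xr)))
        df$.y <- droplevels(yr)
        with_local_seed(s, rpart::rpart(.y ~ ., data = df, method = "class",
                                        control = rpart::rpart.control(
                                          maxdepth = 1L, minsplit = 2L, cp = 0,
                                          xval = 0L)))
      }
      base_predict <- function(m, Xn) {
        df <- as.data.frame(Xn)
        names(df) <- paste0("x", seq_len(ncol(Xn)))
        stats::predict(m, df, type = "class")
      }
      return(structure(list(ensemble = adaboost_fit(table, base_fit,
                                                    base_predict, T = T,
                                                    seed = seed),
                            method = method),
                       class = "baseline_model"))
    })
  structure(list(model = model, method = method, levels = levels(y)),
            class = "baseline_model")
}

#' @export
predict.baseline_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "feature_table")) newdata$values else as.matrix(newdata)
  switch(object$method,
    rf = with_local_seed(2024L, predict(object$model, X)),
    dt = {
      df <- as.data.frame(X)
      names(df) <- paste0("x", seq_len(ncol(X)))
      stats::predict(object$model, df, type = "class")
    },
    nbc = predict(object$model, as.data.frame(X)),
    adaboost = predict(object$ensemble, X))
}
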