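# Maximum-uncertainty linear discriminant analysis: the within-class scatter
# is regularized by raising its sub-mean eigenvalues to the mean eigenvalue,
# stabilizing the inversion while leaving dominant directions untouched.

#' Maximum-uncertainty eigenvalue regularization
#'
#' Replaces every eigenvalue below the mean eigenvalue by the mean:
#' `lambda* = max(lambda, mean(lambda))`. Eigenvalues at or above the mean are
#' unchanged.
#'
#' @param lambda numeric vector of eigenvalues.
#' @return The regularized spectrum.
#' @export
regularize_spectrum <- function(lambda) {
  pmax(lambda, mean(lambda))
}

scatter_matrices <- function(X, y) {
  classes <- levels(y)
  mu <- colMeans(X)
  d <- ncol(X)
  Mw <- matrix(0, d, d)
  Mb <- matrix(0, d, d)
  for (cl in classes) {
    Xi <- X[y == cl, , drop = FALSE]
    mui <- colMeans(Xi)
    Xc <- sweep(Xi, 2, mui)
    Mw <- Mw + t(Xc) %*% Xc
    Mb <- Mb + nrow(Xi) * tcrossprod(mui - mu)
  }
  list(Mw = Mw, Mb = Mb)
}

#' Fit a MULDA classifier
#'
#' Computes within- and between-class scatter, scales the within-class
#' scatter to `M_q = M_w / (n - c)`, eigendecomposes, regularizes the
#' spectrum with [regularize_spectrum()], rebuilds
#' `M_w* = phi Lambda* phi^T (n - c)`, and takes the leading `c - 1`
#' eigenvectors of `solve(M_w*) %*% M_b` as discriminant vectors. Samples are
#' classified by k-nearest neighbours in the discriminant projection.
#'
#' @param table a [feature_table()] with `n > c` rows.
#' @param knn_k neighbour count for prediction.
#' @param seed RNG seed for k-NN tie-breaking.
#' @return An object of class `mulda_model`.
#' @export
mulda_fit <- function(table, knn_k = 10L, seed = 1L) {
  X <- table$values
  y <- droplevels(table$labels)
  n <- nrow(X)
  c_ <- nlevels(y)
  if (n <= c_) stopf("need more samples (%d) than classes (%d)", n, c_)
  if (c_ < 2L) stopf("need at least two classes")
  sc <- scatter_matrices(X, y)
  Mq <- sc$Mw / (n - c_)
  eig <- eigen((Mq + t(Mq)) / 2, symmetric = TRUE)
  lambda <- eig$values
  lambda_star <- regularize_spectrum(lambda)
  if (all(lambda_star <= 0)) stopf("within-class scatter is identically zero")
  Mw_star <- eig$vectors %*% diag(lambda_star, length(lambda_star)) %*%
    t(eig$vectors) * (n - c_)
  Wmat <- tryCatch(solve(Mw_star, sc$Mb),
                   error = function(e) stopf("regularized scatter singular: %s",
                                             conditionMessage(e)))
  de <- eigen(Wmat)
  ord <- order(Re(de$values), decreasing = TRUE)
  V <- Re(de$vectors[, ord[seq_len(c_ - 1L)], drop = FALSE])
  V <- apply(V, 2, function(v) v / sqrt(sum(v^2)))
  V <- matrix(V, ncol = c_ - 1L)
  proj <- X %*% V
  structure(list(discriminants = V, eigenvalues = lambda,
                 eigenvalues_reg = lambda_star,
                 lambda_bar = mean(lambda),
                 train_projections = proj, train_labels = y,
                 knn_k = knn_k, seed = seed),
            class = "mulda_model")
}

#' @export
predict.mulda_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "feature_table")) newdata$values else as.matrix(newdata)
  proj <- X %*% object$discriminants
  knn_predict(object$train_projections, proj, object$train_labels,
              object$knn_k, derive_seed(object$seed, 2024L))
}

#' @export
print.mulda_model <- function(x, ...) {
  cat(sprintf("<mulda_model> %d discriminant vector(s), mean eigenvalue %.4g, k-NN k = %d\n",
              ncol(x$discriminants), x$lambda_bar, x$knn_k))
  invisible(x)
}
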