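# Kernel principal components. The kernel matrix is double-centered and
# eigendecomposed; projections of new points use the dual coefficients.
# The linear kernel reproduces classical PCA scores up to component sign.

kernel_matrix <- function(X, Y, kernel, params) {
  switch(kernel,
    linear = X %*% t(Y),
    gaussian = {
      d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * X %*% t(Y)
      d2[d2 < 0] <- 0
      exp(-d2 / (2 * params$bandwidth^2))
    },
    polynomial = (X %*% t(Y) / params$scale + 1)^params$degree,
    stopf("unsupported kernel '%s'", kernel))
}

#' Fit kernel PCA
#'
#' Builds the n x n kernel matrix, double-centers it in feature space,
#' eigendecomposes, and retains the `n_components` leading components. With
#' the linear kernel the training projections equal classical PCA scores up to
#' per-component sign; eigenvalues are reported on the covariance scale
#' (divided by n - 1), so the variance of each training projection equals its
#' eigenvalue.
#'
#' @param X numeric matrix (n x d) of training points.
#' @param kernel `"linear"`, `"gaussian"` or `"polynomial"`.
#' @param n_components number of components (<= min(n, d) for the linear
#'   kernel, <= n otherwise).
#' @param params kernel parameters: `bandwidth` (gaussian; default median
#'   pairwise distance), `degree` and `scale` (polynomial).
#' @param tol relative tolerance below which negative eigenvalues are treated
#'   as numerical error.
#' @return An object of class `kpca_model`.
#' @export
kpca_fit <- function(X, kernel = "linear", n_components = 4L,
                     params = list(), tol = 1e-8) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (kernel == "gaussian" && is.null(params$bandwidth)) {
    d2 <- stats::dist(X[seq_len(min(n, 200L)), , drop = FALSE])
    params$bandwidth <- max(stats::median(d2), 1e-8)
  }
  if (kernel == "polynomial") {
    params$degree <- params$degree %||% 3
    params$scale <- params$scale %||% ncol(X)
  }
  cap <- if (kernel == "linear") min(n, ncol(X)) else n
  if (!is_count(n_components) || n_components > cap) {
    stopf("n_components must be a count <= %d for the %s kernel", cap, kernel)
  }
  K <- kernel_matrix(X, X, kernel, params)
  if (max(abs(K - t(K))) > 1e-10 * max(abs(K))) stopf("kernel matrix not symmetric")
  rm_ <- colMeans(K)
  gm <- mean(K)
  Kc <- K - outer(rep(1, n), rm_) - outer(rm_, rep(1, n)) + gm
  Kc <- (Kc + t(Kc)) / 2
  eig <- eigen(Kc, symmetric = TRUE)
  if (min(eig$values) < -tol * max(abs(eig$values), 1)) {
    stopf("kernel matrix not positive semi-definite beyond tolerance")
  }
  lam <- pmax(eig$values[seq_len(n_components)], 0)
  if (any(lam <= n * 1e-12)) {
    stopf("requested %d components but centered kernel rank is lower", n_components)
  }
  U <- eig$vectors[, seq_len(n_components), drop = FALSE]
  # Dual coefficients normalized so projection = Kc %*% dual has variance
  # lam / (n - 1) per component.
  dual <- sweep(U, 2, sqrt(lam), "/")
  structure(list(kernel = kernel, params = params, n_components = n_components,
                 X_train = X, dual = dual, row_means = rm_, grand_mean = gm,
                 eigenvalues = lam / (n - 1),
                 train_projections = sweep(U, 2, sqrt(lam), "*")),
            class = "kpca_model")
}

#' Project new points with a fitted kernel PCA model
#'
#' @param model a `kpca_model`.
#' @param X numeric matrix (m x d) of new points.
#' @return An m x n_components matrix of projections.
#' @export
kpca_transform <- function(model, X) {
  X <- as.matrix(X)
  Kn <- kernel_matrix(X, model$X_train, model$kernel, model$params)
  n <- nrow(model$X_train)
  Knc <- Kn - outer(rowMeans(Kn), rep(1, n)) -
    outer(rep(1, nrow(X)), model$row_means) + model$grand_mean
  Knc %*% model$dual
}

#' @export
print.kpca_model <- function(x, ...) {
  cat(sprintf("<kpca_model> kernel = %s, %d components, eigenvalues: %s\n",
              x$kernel, x$n_components,
              paste(signif(x$eigenvalues, 4), collapse = ", ")))
  invisible(x)
}

#' PCA/KPCA features from a descriptor table
#'
#' Fits [kpca_fit()] on the table (linear kernel with 4 components by
#' default — classical PCA as the linear-kernel special case) and returns the
#' projected table together with the model for projecting held-out rows.
#'
#' @param table a [feature_table()] of raw per-segment descriptors.
#' @param kernel,n_components,params see [kpca_fit()].
#' @return A list with `table` (projected [feature_table()]) and `model`.
#' @export
pca_or_kpca_features <- function(table, kernel = "linear", n_components = 4L,
                                 params = list()) {
  model <- kpca_fit(table$values, kernel, n_components, params)
  proj <- model$train_projections
  feature_table(proj, table$labels, paste0("kpc", seq_len(ncol(proj))),
                provenance = list(extractor = if (kernel == "linear") "pca/kpca-linear"
                                  else paste0("kpca-", kernel),
                                  n_components = n_components)) -> out
  list(table = out, model = model)
}
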