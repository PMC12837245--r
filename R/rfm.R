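# Random feature mapping: q groups of random linear maps + ReLU feature
# nodes, fine-tuned into sparse features by a lasso-based autoencoding step
# (coordinate descent on ||Z W - X||^2 + gamma * ||W||_1).

relu <- function(x) pmax(x, 0)

#' Lasso by coordinate descent
#'
#' Minimizes `sum((y - Z beta)^2) + gamma * sum(abs(beta))` (no intercept).
#' At `gamma = 0` the solution coincides with ordinary least squares.
#'
#' @param Z design matrix (n x p).
#' @param y response vector.
#' @param gamma non-negative l1 penalty.
#' @param max_iter,tol convergence controls (max coordinate sweeps; stop when
#'   the largest coefficient update falls below `tol`).
#' @return Coefficient vector of length p.
#' @export
lasso_cd <- function(Z, y, gamma, max_iter = 500L, tol = 1e-10) {
  if (gamma < 0) stopf("gamma must be >= 0")
  p <- ncol(Z)
  beta <- numeric(p)
  cn <- colSums(Z^2)
  r <- y
  soft <- function(z, g) sign(z) * pmax(abs(z) - g, 0)
  for (it in seq_len(max_iter)) {
    delta_max <- 0
    for (j in seq_len(p)) {
      if (cn[j] == 0) next
      zj <- Z[, j]
      rho <- sum(zj * r) + cn[j] * beta[j]
      bj <- soft(rho, gamma / 2) / cn[j]
      d <- bj - beta[j]
      if (d != 0) {
        r <- r - zj * d
        beta[j] <- bj
        delta_max <- max(delta_max, abs(d))
      }
    }
    if (delta_max < tol) break
  }
  beta
}

#' Fit a random feature mapping
#'
#' Generates `q` groups of `n_per_group` random linear feature nodes with ReLU
#' activation, then fine-tunes each group's weights with the lasso
#' autoencoding objective: the raw group output `Z` is regressed onto the
#' input `X` with an l1 penalty, and the transposed sparse solution replaces
#' the random weights. Mapped features are `relu(X W_ft + b)`.
#'
#' @param X numeric matrix (n x d); expected standardized.
#' @param q number of feature-node groups.
#' @param n_per_group neurons per group.
#' @param gamma lasso penalty (>= 0).
#' @param seed RNG seed for the random weights.
#' @return An object of class `rfm_model` with per-group weights and biases.
#' @export
rfm_fit <- function(X, q = 10L, n_per_group = 8L, gamma = 0.01, seed = 1L) {
  if (gamma < 0) stopf("gamma must be >= 0")
  X <- as.matrix(X)
  d <- ncol(X)
  groups <- with_local_seed(seed, lapply(seq_len(q), function(i) {
    W <- matrix(stats::rnorm(d * n_per_group), d, n_per_group)
    b <- stats::rnorm(n_per_group)
    Zraw <- relu(X %*% W + matrix(b, nrow(X), n_per_group, byrow = TRUE))
    # Sparse autoencoding fine-tune: Z A ~ X columnwise, W_ft = t(A).
    A <- vapply(seq_len(d), function(jj) lasso_cd(Zraw, X[, jj], gamma),
                numeric(n_per_group))
    list(W = t(as.matrix(A)), b = b)            # W_ft: d x n_per_group
  }))
  structure(list(groups = groups, q = q, n_per_group = n_per_group,
                 gamma = gamma, d_in = d, seed = seed),
            class = "rfm_model")
}

#' Map data through a fitted random feature mapping
#'
#' @param model an `rfm_model`.
#' @param X numeric matrix with the training dimensionality.
#' @return An n x (q * n_per_group) non-negative feature matrix.
#' @export
rfm_transform <- function(model, X) {
  X <- as.matrix(X)
  do.call(cbind, lapply(model$groups, function(g) {
    relu(X %*% g$W + matrix(g$b, nrow(X), model$n_per_group, byrow = TRUE))
  }))
}

#' RFM features from a descriptor table
#'
#' @param table a standardized [feature_table()] of raw per-segment
#'   descriptors.
#' @param q,n_per_group,gamma,seed see [rfm_fit()].
#' @return A list with `table` (mapped [feature_table()]) and `model`.
#' @export
rfm_features <- function(table, q = 10L, n_per_group = 8L, gamma = 0.01,
                         seed = 1L) {
  model <- rfm_fit(table$values, q, n_per_group, gamma, seed)
  Z <- rfm_transform(model, table$values)
  nm <- as.vector(outer(seq_len(n_per_group), seq_len(q),
                        function(k, g) sprintf("rfm_g%d_n%d", g, k)))
  out <- feature_table(Z, table$labels, nm,
                       provenance = list(extractor = "rfm", q = q,
                                         n_per_group = n_per_group,
                                         gamma = gamma))
  list(table = out, model = model)
}
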