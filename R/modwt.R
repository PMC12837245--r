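# Maximal-overlap (undecimated) discrete wavelet transform. Unlike the
# decimated DWT, every coefficient band has the same length as the input and
# the transform is shift-invariant and energy-preserving.

# Daubechies scaling filters (orthonormal, sum = sqrt(2)).
wavelet_filters <- function(wavelet) {
  g <- switch(wavelet,
    haar = c(1, 1) / sqrt(2),
    db2 = c(0.48296291314469025, 0.836516303737469,
            0.22414386804185735, -0.12940952255092145),
    db4 = c(0.23037781330885523, 0.7148465705525415, 0.6308807679295904,
            -0.02798376941698385, -0.18703481171888114, 0.030841381835986965,
            0.032883011666982945, -0.010597401784997278),
    stopf("unsupported wavelet '%s' (use haar, db2 or db4)", wavelet))
  L <- length(g)
  h <- rev(g) * (-1)^(seq_len(L) - 1)    # quadrature mirror filter
  list(g = g, h = h)
}

# Circularly lag a vector by `shift` samples: out[t] = v[(t - shift) mod N].
circ_lag <- function(v, shift) {
  N <- length(v)
  v[((seq_len(N) - 1 - shift) %% N) + 1]
}

# w[t] = sum_l f[l] v[(t - stride*(l-1)) mod N]
circ_filter <- function(v, f, stride) {
  out <- numeric(length(v))
  for (l in seq_along(f)) out <- out + f[l] * circ_lag(v, stride * (l - 1))
  out
}

# Adjoint direction used by the inverse: out[t] = sum_l f[l] v[(t + stride*(l-1)) mod N]
circ_filter_adj <- function(v, f, stride) {
  out <- numeric(length(v))
  for (l in seq_along(f)) out <- out + f[l] * circ_lag(v, -stride * (l - 1))
  out
}

#' Maximal-overlap discrete wavelet transform
#'
#' Pyramid MODWT with circular boundary handling. Returns `levels` detail
#' bands plus the final smooth band, each of the input length; the transform
#' conserves energy exactly and [imodwt()] inverts it.
#'
#' @param x numeric signal.
#' @param wavelet `"haar"`, `"db2"` or `"db4"`.
#' @param levels decomposition depth (>= 1).
#' @return A list with `W` (levels x N detail coefficient matrix), `V`
#'   (length-N smooth band), `wavelet`, `levels`.
#' @export
modwt <- function(x, wavelet = "db4", levels = 5L) {
  if (!is_count(levels)) stopf("levels must be a count >= 1")
  filt <- wavelet_filters(wavelet)
  N <- length(x)
  support <- (2^levels - 1) * (length(filt$g) - 1) + 1
  if (N < support) {
    stopf("signal length %d below filter support %d at level %d", N, support, levels)
  }
  gt <- filt$g / sqrt(2)
  ht <- filt$h / sqrt(2)
  W <- matrix(0, levels, N)
  v <- x
  for (j in seq_len(levels)) {
    stride <- 2^(j - 1)
    W[j, ] <- circ_filter(v, ht, stride)
    v <- circ_filter(v, gt, stride)
  }
  list(W = W, V = v, wavelet = wavelet, levels = levels)
}

#' Inverse maximal-overlap discrete wavelet transform
#'
#' @param decomp output of [modwt()].
#' @return The reconstructed signal.
#' @export
imodwt <- function(decomp) {
  filt <- wavelet_filters(decomp$wavelet)
  gt <- filt$g / sqrt(2)
  ht <- filt$h / sqrt(2)
  v <- decomp$V
  for (j in rev(seq_len(decomp$levels))) {
    stride <- 2^(j - 1)
    v <- circ_filter_adj(v, gt, stride) + circ_filter_adj(decomp$W[j, ], ht, stride)
  }
  v
}

band_stats <- function(w, total_energy) {
  e <- sum(w^2)
  c(mav = mean(abs(w)), var = stats::var(w),
    energy_frac = if (total_energy > 0) e / total_energy else 0,
    skew = e1071::skewness(w), kurt = e1071::kurtosis(w))
}

#' MODWT band-statistics features
#'
#' Each segment is decomposed into `levels` detail bands plus the smooth band;
#' each band is summarized by mean absolute value, variance, energy fraction,
#' skewness and excess kurtosis, giving `5 * (levels + 1)` features per
#' segment.
#'
#' @param segments a `segment_set`.
#' @param wavelet wavelet name (see [modwt()]).
#' @param levels decomposition depth.
#' @return A [feature_table()].
#' @export
modwt_features <- function(segments, wavelet = "db4", levels = 5L) {
  feats <- t(apply(segments$segments, 1, function(x) {
    d <- modwt(x, wavelet, levels)
    total <- sum(d$W^2) + sum(d$V^2)
    unlist(lapply(seq_len(levels), function(j) band_stats(d$W[j, ], total)),
           use.names = FALSE) |>
      c(band_stats(d$V, total))
  }))
  nm <- c(as.vector(outer(c("mav", "var", "energy_frac", "skew", "kurt"),
                          paste0("d", seq_len(levels)),
                          function(s, b) paste(b, s, sep = "_"))),
          paste("smooth", c("mav", "var", "energy_frac", "skew", "kurt"), sep = "_"))
  feats[!is.finite(feats)] <- 0
  feature_table(feats, segments$labels, nm,
                provenance = list(extractor = "modwt", wavelet = wavelet,
                                  levels = levels))
}
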