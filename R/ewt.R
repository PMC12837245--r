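# Empirical wavelet transform: a data-adaptive filter bank whose band edges
# are the midpoints between adjacent local maxima of the magnitude spectrum.
# Filters are Meyer-type raised-cosine bandpasses built as a partition of
# unity in frequency, so the plain sum of the extracted modes reconstructs the
# input exactly.

# Indices of local maxima of a vector (strictly above the left neighbour,
# at least the right neighbour); endpoints excluded.
local_maxima <- function(m) {
  n <- length(m)
  if (n < 3L) return(integer())
  which(m[2:(n - 1)] > m[1:(n - 2)] & m[2:(n - 1)] >= m[3:n]) + 1L
}

#' Empirical wavelet band boundaries
#'
#' Locates the `n_modes` largest local maxima of the magnitude spectrum (DC
#' excluded) and places the `n_modes - 1` band boundaries at the midpoints of
#' adjacent retained maxima, so one band surrounds each maximum. If fewer
#' maxima exist, as many modes as found are used with a warning.
#'
#' @param x numeric signal.
#' @param fs sampling rate in Hz.
#' @param n_modes requested number of modes (>= 1).
#' @return A list with `boundaries` (Hz, interior only), `peaks` (Hz) and
#'   `n_modes` actually used.
#' @export
ewt_boundaries <- function(x, fs, n_modes) {
  if (!is_count(n_modes)) stopf("n_modes must be a count >= 1")
  N <- length(x)
  half <- floor(N / 2) + 1L
  mag <- Mod(stats::fft(x))[seq_len(half)]
  freqs <- (seq_len(half) - 1) * fs / N
  mag[1] <- 0                                    # ignore DC
  peaks <- local_maxima(mag)
  # drop numerical-floor maxima (spectral leakage / round-off)
  peaks <- peaks[mag[peaks] > 1e-3 * max(mag)]
  if (n_modes == 1L || length(peaks) < 2L) {
    if (n_modes > 1L) {
      warnf("ewt: %d spectral maxima found; falling back to 1 mode", length(peaks))
    }
    return(list(boundaries = numeric(), peaks = freqs[peaks], n_modes = 1L))
  }
  want <- n_modes
  if (length(peaks) < want) {
    warnf("ewt: only %d spectral maxima; using %d modes instead of %d",
          length(peaks), length(peaks), n_modes)
    want <- length(peaks)
  }
  top <- peaks[order(mag[peaks], decreasing = TRUE)][seq_len(want)]
  top <- sort(freqs[top])
  boundaries <- (top[-1] + top[-length(top)]) / 2
  list(boundaries = boundaries, peaks = top, n_modes = length(boundaries) + 1L)
}

# Raised-cosine step from 0 to 1 over [b - tau, b + tau].
rc_step <- function(f, b, tau) {
  s <- (f - (b - tau)) / (2 * tau)
  s <- pmin(pmax(s, 0), 1)
  sin(pi / 2 * s)^2
}

#' Empirical wavelet decomposition
#'
#' Builds the adaptive raised-cosine filter bank on [ewt_boundaries()] and
#' extracts the modes by frequency-domain filtering. Because the filters sum
#' to one at every frequency, `colSums` of the modes equals the input to
#' machine precision.
#'
#' @param x numeric signal.
#' @param fs sampling rate in Hz.
#' @param n_modes requested number of modes.
#' @param transition relative half-width of each boundary transition (fraction
#'   of the boundary frequency, capped by the spacing to adjacent boundaries).
#' @return A list with `modes` (n_modes x N matrix), `boundaries`, `fs`.
#' @export
ewt_decompose <- function(x, fs, n_modes = 5L, transition = 0.2) {
  bd <- ewt_boundaries(x, fs, n_modes)
  N <- length(x)
  freqs_all <- (seq_len(N) - 1) * fs / N
  freqs <- pmin(freqs_all, fs - freqs_all)       # two-sided |frequency|
  edges <- bd$boundaries
  M <- length(edges) + 1L
  X <- stats::fft(x)
  modes <- matrix(0, M, N)
  gaps <- diff(c(0, edges, fs / 2))
  low <- matrix(1, M, N)                        # cumulative low-pass masks
  prev <- rep(1, N)
  for (m in seq_len(M)) {
    if (m <= length(edges)) {
      b <- edges[m]
      tau <- min(transition * b, 0.45 * gaps[m], 0.45 * gaps[m + 1])
      hi <- rc_step(freqs, b, tau)               # 0 below b, 1 above
      filt <- prev * (1 - hi)
      prev <- prev * hi
    } else {
      filt <- prev
    }
    modes[m, ] <- Re(stats::fft(X * filt, inverse = TRUE)) / N
  }
  list(modes = modes, boundaries = edges, peaks = bd$peaks, fs = fs)
}

hjorth_mobility <- function(x) {
  v <- stats::var(x)
  if (v == 0) return(0)
  sqrt(stats::var(diff(x)) / v)
}

spectral_centroid <- function(x, fs) {
  N <- length(x)
  half <- floor(N / 2) + 1L
  p <- Mod(stats::fft(x))[seq_len(half)]^2
  f <- (seq_len(half) - 1) * fs / N
  if (sum(p) == 0) return(0)
  sum(f * p) / sum(p)
}

#' EWT per-mode features
#'
#' Each segment is decomposed with [ewt_decompose()]; each mode contributes
#' its energy fraction, spectral centroid, variance and Hjorth mobility
#' (4 features per mode). Segments that fall back to fewer modes are padded
#' with zeros so the feature length stays fixed.
#'
#' @param segments a `segment_set`.
#' @param n_modes requested number of modes.
#' @return A [feature_table()].
#' @export
ewt_features <- function(segments, n_modes = 5L) {
  fs <- segments$fs
  feats <- t(apply(segments$segments, 1, function(x) {
    dec <- ewt_decompose(x, fs, n_modes)
    total <- sum(x^2)
    out <- matrix(0, 4, n_modes)
    for (m in seq_len(min(nrow(dec$modes), n_modes))) {
      w <- dec$modes[m, ]
      out[, m] <- c(if (total > 0) sum(w^2) / total else 0,
                    spectral_centroid(w, fs), stats::var(w),
                    hjorth_mobility(w))
    }
    as.vector(out)
  }))
  nm <- as.vector(outer(c("energy_frac", "centroid", "var", "mobility"),
                        paste0("mode", seq_len(n_modes)),
                        function(s, b) paste(b, s, sep = "_")))
  feats[!is.finite(feats)] <- 0
  feature_table(feats, segments$labels, nm,
                provenance = list(extractor = "ewt", n_modes = n_modes))
}
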