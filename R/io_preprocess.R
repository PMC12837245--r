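# Waveform/manifest I/O, ICA artifact cleaning, fixed-window segmentation and
# leakage-safe feature standardization.

#' Write a cohort as delimited-text waveforms plus a manifest
#'
#' One waveform file per subject (one sample per row, one column per channel,
#' no header) and a `manifest.csv` with columns
#' `subject_id,file,label,fs[,hr]`.
#'
#' @param cohort a list of `bcg_record` objects.
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- lapply(cohort, function(rec) {
    file <- paste0(rec$subject_id, ".txt")
    m <- do.call(cbind, rec$channels)
    utils::write.table(format(m, digits = 7, scientific = FALSE, trim = TRUE),
                       file.path(dir, file), row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
    data.frame(subject_id = rec$subject_id, file = file, label = rec$label,
               fs = rec$fs, hr = rec$demographics$hr %||% NA_real_)
  })
  manifest <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort from a manifest of delimited-text waveform files
#'
#' The manifest must have a header with at least
#' `subject_id,file,label,fs`; waveform files are one- or two-column
#' delimited text, no header, one sample per row. Malformed rows are reported
#' with their position and subject.
#'
#' @param manifest_path path to the manifest file.
#' @return A `bcg_cohort` list of `bcg_record` objects.
#' @export
read_cohort <- function(manifest_path) {
  if (!file.exists(manifest_path)) stopf("manifest not found: %s", manifest_path)
  manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  required <- c("subject_id", "file", "label", "fs")
  missing <- setdiff(required, names(manifest))
  if (length(missing)) stopf("manifest missing columns: %s", paste(missing, collapse = ", "))
  base <- dirname(manifest_path)
  recs <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    path <- file.path(base, row$file)
    if (!file.exists(path)) {
      stopf("waveform file for subject '%s' not found (manifest line %d): %s",
            row$subject_id, i + 1L, path)
    }
    m <- tryCatch(
      as.matrix(utils::read.table(path, header = FALSE,
                                  colClasses = "numeric")),
      error = function(e) stopf(
        "non-numeric sample in waveform of subject '%s' (%s): %s",
        row$subject_id, path, conditionMessage(e)))
    if (any(!is.finite(m))) {
      bad <- which(!is.finite(m))[1]
      stopf("non-finite sample at position %d in waveform of subject '%s'",
            bad, row$subject_id)
    }
    if (!is_number(row$fs) || row$fs <= 0) {
      stopf("invalid fs for subject '%s' (manifest line %d)", row$subject_id, i + 1L)
    }
    demo <- list()
    for (f in intersect(c("age", "bmi", "hr", "sbp", "dbp"), names(manifest))) {
      demo[[f]] <- row[[f]]
    }
    recs[[i]] <- structure(
      list(subject_id = as.character(row$subject_id),
           channels = lapply(seq_len(ncol(m)), function(j) unname(m[, j])),
           fs = as.numeric(row$fs),
           label = as.character(as_class_factor(row$label)),
           demographics = demo),
      class = "bcg_record")
  }
  structure(recs, class = "bcg_cohort")
}

# FastICA-style symmetric fixed-point unmixing (tanh contrast) on whitened
# data. Returns sources S (components x n) and mixing so that
# X_centered = mixing %*% S.
fastica_unmix <- function(X, n_components, seed, max_iter = 200, tol = 1e-8) {
  # X: channels x n
  mu <- rowMeans(X)
  Xc <- X - mu
  C <- Xc %*% t(Xc) / ncol(Xc)
  ev <- eigen(C, symmetric = TRUE)
  if (any(ev$values < 1e-12 * max(ev$values))) {
    stopf("degenerate channel covariance (zero-variance or collinear channels)")
  }
  K <- diag(1 / sqrt(ev$values[seq_len(n_components)]), n_components) %*%
    t(ev$vectors[, seq_len(n_components), drop = FALSE])
  Z <- K %*% Xc                                 # whitened, components x n
  W <- with_local_seed(seed, matrix(stats::rnorm(n_components^2), n_components))
  orthonormalize <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }
  W <- orthonormalize(W)
  for (it in seq_len(max_iter)) {
    WZ <- W %*% Z
    G <- tanh(WZ)
    gprime <- 1 - G^2
    W1 <- (G %*% t(Z)) / ncol(Z) - diag(rowMeans(gprime), n_components) %*% W
    W1 <- orthonormalize(W1)
    if (max(abs(abs(diag(W1 %*% t(W))) - 1)) < tol) {
      W <- W1
      break
    }
    W <- W1
  }
  S <- W %*% Z
  # X_centered = t(K) pseudo-inverse path: mixing = pinv(W %*% K)
  A <- t(qr.solve(W %*% K, diag(nrow(X))))      # channels x components
  list(S = S, mixing = t(A), mean = mu)
}

#' ICA-based artifact cleaning of a multi-channel record
#'
#' Unmixes the channels with a FastICA-style fixed-point algorithm, zeroes
#' independent components whose excess kurtosis exceeds `kurtosis_threshold`
#' (an impulsive-artifact heuristic), and re-projects to channel space.
#' Single-channel records pass through unchanged with a warning.
#'
#' @param record a `bcg_record`.
#' @param n_components number of components (defaults to the channel count).
#' @param kurtosis_threshold excess-kurtosis cutoff above which a component is
#'   treated as artifact and zeroed.
#' @param seed RNG seed for the unmixing initialization.
#' @return A `bcg_record` with cleaned channels of the original length.
#' @export
ica_clean <- function(record, n_components = NULL, kurtosis_threshold = 10,
                      seed = 1L) {
  nch <- length(record$channels)
  if (nch < 2L) {
    warnf("ica_clean: record '%s' has a single channel; returning unchanged",
          record$subject_id)
    return(record)
  }
  if (is.null(n_components)) n_components <- nch
  if (n_components > nch) {
    stopf("n_components (%d) exceeds number of channels (%d)", n_components, nch)
  }
  X <- do.call(rbind, record$channels)
  if (any(apply(X, 1, stats::sd) == 0)) {
    stopf("zero-variance channel in record '%s'", record$subject_id)
  }
  fit <- fastica_unmix(X, n_components, seed)
  kurt <- apply(fit$S, 1, function(s) mean((s - mean(s))^4) / stats::var(s)^2 - 3)
  keep <- kurt <= kurtosis_threshold
  S2 <- fit$S * keep
  Xc <- fit$mixing %*% S2 + fit$mean
  record$channels <- lapply(seq_len(nch), function(j) unname(Xc[j, ]))
  record
}

#' Segment a record into fixed non-overlapping windows
#'
#' Trailing partial windows are dropped; each segment inherits the record's
#' label and subject id. Segmentation uses the record's first channel.
#'
#' @param record a `bcg_record`.
#' @param window_seconds window length in seconds.
#' @return A `segment_set`: `segments` matrix (n_segments x window length),
#'   `fs`, `labels`, `subject_ids`.
#' @export
segment_record <- function(record, window_seconds = 300) {
  L <- round(window_seconds * record$fs)
  x <- record$channels[[1]]
  if (length(x) < L) {
    stopf("record '%s' (%d samples) shorter than one %g-s window (%d samples)",
          record$subject_id, length(x), window_seconds, L)
  }
  k <- length(x) %/% L
  segs <- matrix(x[seq_len(k * L)], nrow = k, ncol = L, byrow = TRUE)
  structure(list(segments = segs, fs = record$fs,
                 labels = as_class_factor(rep(record$label, k)),
                 subject_ids = rep(record$subject_id, k)),
            class = "segment_set")
}

#' Segment every record of a cohort
#'
#' @param cohort a `bcg_cohort`.
#' @param window_seconds window length in seconds.
#' @return A combined `segment_set` over all records.
#' @export
segment_cohort <- function(cohort, window_seconds = 300) {
  parts <- lapply(cohort, segment_record, window_seconds = window_seconds)
  structure(list(segments = do.call(rbind, lapply(parts, `[[`, "segments")),
                 fs = parts[[1]]$fs,
                 labels = as_class_factor(unlist(lapply(parts, function(p) as.character(p$labels)))),
                 subject_ids = unlist(lapply(parts, `[[`, "subject_ids"))),
            class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf("<segment_set> %d segments x %d samples, fs = %g Hz, %d subjects\n",
              nrow(x$segments), ncol(x$segments), x$fs,
              length(unique(x$subject_ids))))
  invisible(x)
}

#' Z-score standardization fitted on a row subset
#'
#' Column means/SDs are estimated on `fit_rows` only and applied to all rows,
#' so cross-validation folds can standardize without test-fold leakage.
#' Zero-SD columns are mapped to 0 with a warning.
#'
#' @param table a [feature_table()].
#' @param fit_rows indices of the rows used to estimate the scaler (default:
#'   all rows).
#' @param scaler optionally, a previously fitted scaler (`center`/`scale`) to
#'   apply instead of fitting.
#' @return A list with `table` (standardized [feature_table()]) and `scaler`
#'   (`center` and `scale` vectors).
#' @export
standardize <- function(table, fit_rows = seq_len(nrow(table$values)),
                        scaler = NULL) {
  if (is.null(scaler)) {
    if (length(fit_rows) == 0L) stopf("fit_rows must be non-empty")
    sub <- table$values[fit_rows, , drop = FALSE]
    center <- colMeans(sub)
    scale <- apply(sub, 2, stats::sd)
    if (length(fit_rows) == 1L) scale[] <- 0
    if (any(scale == 0)) {
      warnf("standardize: %d constant column(s) mapped to 0", sum(scale == 0))
    }
    scaler <- list(center = center, scale = scale)
  }
  sc <- ifelse(scaler$scale == 0, 1, scaler$scale)
  v <- sweep(sweep(table$values, 2, scaler$center, "-"), 2, sc, "/")
  v[, scaler$scale == 0] <- 0
  out <- feature_table(v, table$labels, table$feature_names, table$provenance)
  list(table = out, scaler = scaler)
}
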