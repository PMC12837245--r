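#' Construct a feature table
#'
#' The lingua franca between pipeline stages: a numeric samples-by-features
#' matrix with unique feature names, per-row class labels and a provenance
#' record describing which extractor produced it.
#'
#' @param values numeric matrix (n samples x d features), no NaN/Inf.
#' @param labels per-row class labels: `"normal"`/`"hypertensive"`, a factor
#'   with those levels, or 0/1 (0 = normal).
#' @param feature_names character vector of d unique names; defaults to the
#'   matrix column names or `f1..fd`.
#' @param provenance named list recording the producing stage and parameters.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(values, labels, feature_names = NULL,
                          provenance = list()) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (ncol(values) < 1L) stopf("feature table needs at least one feature")
  if (any(!is.finite(values))) stopf("feature values must be finite (no NaN/Inf)")
  if (is.null(feature_names)) {
    feature_names <- colnames(values)
    if (is.null(feature_names)) feature_names <- paste0("f", seq_len(ncol(values)))
  }
  if (anyDuplicated(feature_names)) stopf("feature names must be unique")
  if (length(feature_names) != ncol(values)) {
    stopf("feature_names length (%d) != number of columns (%d)",
          length(feature_names), ncol(values))
  }
  labels <- as_class_factor(labels)
  if (length(labels) != nrow(values)) {
    stopf("labels length (%d) != number of rows (%d)", length(labels), nrow(values))
  }
  colnames(values) <- feature_names
  structure(list(values = values, feature_names = feature_names,
                 labels = labels, provenance = provenance),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d samples x %d features (%s)\n",
              nrow(x$values), ncol(x$values),
              if (length(x$provenance)) x$provenance$extractor %||% "unknown"
              else "unspecified"))
  cat("  labels:", paste(sprintf("%s=%d", levels(x$labels), table(x$labels)),
                         collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Row/column subsetting that preserves the class.
subset_table <- function(table, rows = NULL, cols = NULL) {
  v <- table$values
  lab <- table$labels
  if (!is.null(rows)) {
    v <- v[rows, , drop = FALSE]
    lab <- lab[rows]
  }
  if (!is.null(cols)) v <- v[, cols, drop = FALSE]
  feature_table(v, lab, colnames(v), table$provenance)
}

#' Write/read a feature table as delimited text
#'
#' Serialized as comma-separated text with a header of feature names plus a
#' trailing `label` column.
#'
#' @param table a [feature_table()].
#' @param path output file path.
#' @return `write_feature_table` returns `path` invisibly; `read_feature_table`
#'   returns a `feature_table`.
#' @export
write_feature_table <- function(table, path) {
  df <- as.data.frame(table$values)
  df$label <- as.character(table$labels)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"label" %in% names(df)) stopf("no 'label' column in %s", path)
  lab <- df$label
  df$label <- NULL
  feature_table(as.matrix(df), lab, names(df),
                provenance = list(extractor = "file", path = path))
}
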