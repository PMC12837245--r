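# Cross-validated scoring of (extractor x selector x classifier)
# combinations with subject-level stratified folds, the accuracy metric, and
# the feature-statistics battery.

#' Confusion matrix for the binary task
#'
#' Positive class = hypertensive.
#'
#' @param truth,pred factors or label vectors.
#' @return An object of class `confusion_matrix` with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_matrix <- function(truth, pred) {
  truth <- as_class_factor(truth)
  pred <- as_class_factor(pred)
  if (length(truth) != length(pred)) stopf("truth/pred length mismatch")
  structure(list(TP = sum(truth == "hypertensive" & pred == "hypertensive"),
                 TN = sum(truth == "normal" & pred == "normal"),
                 FP = sum(truth == "normal" & pred == "hypertensive"),
                 FN = sum(truth == "hypertensive" & pred == "normal")),
            class = "confusion_matrix")
}

#' Classification accuracy in percent
#'
#' `100 * (TP + TN) / (TP + TN + FP + FN)`.
#'
#' @param cm a [confusion_matrix()].
#' @return Accuracy as a percentage.
#' @export
accuracy <- function(cm) {
  total <- cm$TP + cm$TN + cm$FP + cm$FN
  if (total == 0) stopf("empty confusion matrix")
  100 * (cm$TP + cm$TN) / total
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> TP=%d TN=%d FP=%d FN=%d (accuracy %.2f%%)\n",
              x$TP, x$TN, x$FP, x$FN, accuracy(x)))
  invisible(x)
}

# Raw per-segment descriptors: the intermediate high-dimensional statistics
# fed to PCA/KPCA/RFM (and usable directly as a "raw" extractor).
raw_descriptors <- function(segments) {
  fs <- segments$fs
  bands <- c(0, 2, 5, 10, 20, Inf)
  lags <- pmax(1L, round(c(0.1, 0.2, 0.5) * fs))
  feats <- t(apply(segments$segments, 1, function(x) {
    N <- length(x)
    half <- floor(N / 2) + 1L
    p <- Mod(stats::fft(x))[seq_len(half)]^2
    f <- (seq_len(half) - 1) * fs / N
    ptot <- sum(p)
    bandfrac <- vapply(seq_len(length(bands) - 1L), function(b) {
      if (ptot == 0) return(0)
      sum(p[f >= bands[b] & f < bands[b + 1L]]) / ptot
    }, 0)
    ac <- stats::acf(x, lag.max = max(lags), plot = FALSE)$acf[lags + 1L]
    m <- mean(x); s <- stats::sd(x)
    dx <- diff(x)
    mob <- hjorth_mobility(x)
    comp <- if (mob > 0) hjorth_mobility(dx) / mob else 0
    c(mean = m, sd = s, skew = e1071::skewness(x), kurt = e1071::kurtosis(x),
      p2p = max(x) - min(x), rms = sqrt(mean(x^2)),
      zcr = mean(diff(sign(x - m)) != 0),
      mobility = mob, complexity = comp,
      stats::setNames(bandfrac, paste0("bandfrac", seq_along(bandfrac))),
      stats::setNames(ac, paste0("acf", lags)))
  }))
  feats[!is.finite(feats)] <- 0
  feature_table(feats, segments$labels, colnames(feats),
                provenance = list(extractor = "raw"))
}

default_cv_opts <- function(opts = list()) {
  base <- list(
    kmeans_K = 4L, kmeans_frame_seconds = 2,
    modwt_wavelet = "db4", modwt_levels = 5L,
    ewt_modes = 5L,
    kpca_kernel = "linear", kpca_components = 4L, kpca_params = list(),
    rfm_q = 10L, rfm_n_per_group = 8L, rfm_gamma = 0.01,
    selector_pop = 20L, selector_generations = 20L, selector_bins = 10L,
    fitness_k1 = 0.99, fitness_k2 = 0.01, fitness_folds = 3L,
    knn_k = 10L,
    boost_T = 20L, rf_trees = 20L,
    arima_orders = c(2L, 1L, 2L),
    svm_degree = 3L, svm_cost = 1,
    tw_eta = 0, tw_batch = 1L)
  utils::modifyList(base, opts)
}

EXTRACTORS <- c("kmeans", "modwt", "ewt", "pca", "kpca", "rfm", "raw")
SELECTORS <- c("ig", "btsa", "aoa", "chi2", "pcc", "bpso", "baco", "none")
CLASSIFIERS <- c("adaboost_mulda", "adaboost_rf", "arima_adaboost", "tw_hasvm",
                 "rf", "dt", "nbc", "adaboost")

# Per-segment feature tables that involve no cross-sample fitting can be
# computed once and shared across folds, permutations and grid cells.
base_feature_table <- function(segments, extractor, opts, seed, cache = NULL) {
  key <- switch(extractor, pca = , kpca = , rfm = , raw = "raw", extractor)
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  tab <- switch(key,
    kmeans = kmeans_features(segments, opts$kmeans_K, opts$kmeans_frame_seconds,
                             seed = derive_seed(seed, 1L)),
    modwt = modwt_features(segments, opts$modwt_wavelet, opts$modwt_levels),
    ewt = ewt_features(segments, opts$ewt_modes),
    raw = raw_descriptors(segments))
  if (!is.null(cache)) cache[[key]] <- tab
  tab
}

# Fold-level extraction: standardize with train-row statistics, then fit any
# data-dependent projection (KPCA/RFM) on the training rows only.
fold_features <- function(base_tab, extractor, train, opts, seed) {
  std <- standardize(base_tab, fit_rows = train)
  tab <- std$table
  if (extractor %in% c("pca", "kpca")) {
    kernel <- if (extractor == "pca") "linear" else opts$kpca_kernel
    tr <- subset_table(tab, rows = train)
    model <- kpca_fit(tr$values, kernel, opts$kpca_components, opts$kpca_params)
    proj <- matrix(NA_real_, nrow(tab$values), opts$kpca_components)
    proj[train, ] <- model$train_projections
    rest <- setdiff(seq_len(nrow(tab$values)), train)
    if (length(rest)) proj[rest, ] <- kpca_transform(model, tab$values[rest, , drop = FALSE])
    feature_table(proj, tab$labels, paste0("kpc", seq_len(ncol(proj))),
                  provenance = list(extractor = extractor))
  } else if (extractor == "rfm") {
    tr <- subset_table(tab, rows = train)
    model <- rfm_fit(tr$values, opts$rfm_q, opts$rfm_n_per_group,
                     opts$rfm_gamma, seed = derive_seed(seed, 2L))
    Z <- rfm_transform(model, tab$values)
    feature_table(Z, tab$labels, paste0("rfm", seq_len(ncol(Z))),
                  provenance = list(extractor = "rfm"))
  } else {
    tab
  }
}

fit_selector <- function(train_tab, selector, opts, seed) {
  if (selector == "none") {
    return(new_selection_mask(rep(1L, ncol(train_tab$values)), NA_real_, "none"))
  }
  if (selector == "ig") return(information_gain(train_tab, opts$selector_bins))
  if (selector %in% c("chi2", "pcc")) {
    return(baseline_select(train_tab, selector, bins = opts$selector_bins))
  }
  ev <- fitness_evaluator(train_tab, opts$fitness_k1, opts$fitness_k2,
                          opts$fitness_folds, opts$knn_k, seed)
  switch(selector,
    btsa = btsa_select(train_tab, ev, opts$selector_pop,
                       opts$selector_generations, seed),
    aoa = aoa_select(train_tab, ev, opts$selector_pop,
                     opts$selector_generations, seed),
    bpso = baseline_select(train_tab, "bpso", ev, opts$selector_pop,
                           opts$selector_generations, seed),
    baco = baseline_select(train_tab, "baco", ev, opts$selector_pop,
                           opts$selector_generations, seed),
    stopf("unknown selector '%s'", selector))
}

fit_classifier <- function(train_tab, classifier, opts, seed, arima_train = NULL) {
  switch(classifier,
    adaboost_mulda = hybrid_adaboost_mulda(train_tab, opts$boost_T, opts$knn_k, seed),
    adaboost_rf = hybrid_adaboost_rf(train_tab, opts$boost_T, opts$rf_trees,
                                     seed = seed),
    arima_adaboost = hybrid_arima_adaboost(train_tab, NULL, opts$boost_T,
                                           opts$arima_orders, seed,
                                           arima_feats = arima_train),
    tw_hasvm = tw_hasvm_fit(train_tab, opts$tw_eta, opts$tw_batch, opts$boost_T,
                            opts$svm_degree, opts$svm_cost, seed),
    rf = baseline_classifier(train_tab, "rf", n_trees = opts$rf_trees, seed = seed),
    dt = baseline_classifier(train_tab, "dt", seed = seed),
    nbc = baseline_classifier(train_tab, "nbc", seed = seed),
    adaboost = baseline_classifier(train_tab, "adaboost", T = opts$boost_T,
                                   seed = seed),
    stopf("unknown classifier '%s'", classifier))
}

predict_classifier <- function(model, test_tab, classifier, arima_test = NULL) {
  if (classifier == "arima_adaboost") {
    predict(model, test_tab, arima_feats = arima_test)
  } else {
    predict(model, test_tab)
  }
}

#' Subject-stratified cross-validated pipeline evaluation
#'
#' Partitions subjects (not segments) into stratified folds; per fold, the
#' standardizer, any data-dependent extractor stage (KPCA/RFM), the feature
#' selector and the classifier are fitted on training subjects only and
#' scored on the held-out subjects' segments. Per-segment extraction with no
#' cross-sample fitting (K-means/MODWT/EWT band statistics, raw descriptors,
#' ARIMA coefficients) is computed once up front.
#'
#' @param segments a `segment_set`.
#' @param extractor one of `"kmeans"`, `"modwt"`, `"ewt"`, `"pca"`,
#'   `"kpca"`, `"rfm"`, `"raw"`.
#' @param selector one of `"ig"`, `"btsa"`, `"aoa"`, `"chi2"`, `"pcc"`,
#'   `"bpso"`, `"baco"`, `"none"`.
#' @param classifier one of `"adaboost_mulda"`, `"adaboost_rf"`,
#'   `"arima_adaboost"`, `"tw_hasvm"`, `"rf"`, `"dt"`, `"nbc"`, `"adaboost"`.
#' @param folds number of CV folds.
#' @param seed RNG seed; fold assignment and every fitted stage derive from
#'   it.
#' @param opts named list of stage options (see `default_cv_opts` in the
#'   sources for the full set and defaults).
#' @param cache optional environment reused across calls on the same
#'   `segments` to share per-segment extraction.
#' @param permute_labels if `TRUE`, subject labels are randomly permuted
#'   before fold assignment (the leakage null).
#' @return An object of class `cv_result`.
#' @export
cross_validate <- function(segments, extractor = "modwt", selector = "ig",
                           classifier = "adaboost_mulda", folds = 10L,
                           seed = 1L, opts = list(), cache = NULL,
                           permute_labels = FALSE) {
  extractor <- match.arg(extractor, EXTRACTORS)
  selector <- match.arg(selector, SELECTORS)
  classifier <- match.arg(classifier, CLASSIFIERS)
  opts <- default_cv_opts(opts)
  labels <- segments$labels
  subj <- segments$subject_ids
  if (permute_labels) {
    usub <- unique(subj)
    slab <- labels[match(usub, subj)]
    newlab <- with_local_seed(derive_seed(seed, 555L), sample(as.character(slab)))
    labels <- as_class_factor(newlab[match(subj, usub)])
    segments <- structure(list(segments = segments$segments, fs = segments$fs,
                               labels = labels, subject_ids = subj),
                          class = "segment_set")
  }
  usub <- unique(subj)
  slab <- labels[match(usub, subj)]
  if (min(table(slab)) < folds) {
    stopf("need at least %d subjects per class for %d folds", folds, folds)
  }
  fold_subjects <- stratified_folds(usub, slab, folds, derive_seed(seed, 99L))
  base_tab <- base_feature_table(segments, extractor, opts, seed, cache)
  arima_all <- NULL
  if (classifier == "arima_adaboost") {
    if (!is.null(cache) && !is.null(cache$arima)) {
      arima_all <- cache$arima
    } else {
      arima_all <- arima_descriptors(segments, opts$arima_orders)
      if (!is.null(cache)) cache$arima <- arima_all
    }
  }
  if (permute_labels) {
    base_tab <- feature_table(base_tab$values, labels, base_tab$feature_names,
                              base_tab$provenance)
  }
  fold_results <- vector("list", folds)
  for (fi in seq_len(folds)) {
    test <- which(subj %in% fold_subjects[[fi]])
    train <- setdiff(seq_along(subj), test)
    if (nlevels(droplevels(labels[train])) < 2L) {
      stopf("a class is absent from the training split of fold %d", fi)
    }
    fseed <- derive_seed(seed, 100L + fi)
    tab <- fold_features(base_tab, extractor, train, opts, fseed)
    train_tab <- subset_table(tab, rows = train)
    mask <- fit_selector(train_tab, selector, opts, fseed)
    sel_train <- subset_table(train_tab, cols = mask$mask == 1L)
    sel_test <- subset_table(tab, rows = test, cols = mask$mask == 1L)
    ar_train <- if (is.null(arima_all)) NULL else arima_all[train, , drop = FALSE]
    ar_test <- if (is.null(arima_all)) NULL else arima_all[test, , drop = FALSE]
    model <- fit_classifier(sel_train, classifier, opts, fseed,
                            arima_train = ar_train)
    pred <- predict_classifier(model, sel_test, classifier,
                               arima_test = ar_test)
    cm <- confusion_matrix(labels[test], pred)
    fold_results[[fi]] <- list(cm = cm, accuracy = accuracy(cm), mask = mask$mask,
                               test_subjects = fold_subjects[[fi]])
  }
  accs <- vapply(fold_results, `[[`, 0, "accuracy")
  structure(list(combination = c(extractor = extractor, selector = selector,
                                 classifier = classifier),
                 folds = fold_results, fold_accuracies = accs,
                 mean_accuracy = mean(accs), seed = seed,
                 fold_subjects = fold_subjects, opts = opts,
                 permuted = permute_labels),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s + %s + %s: mean accuracy %.2f%% over %d folds%s\n",
              x$combination["extractor"], x$combination["selector"],
              x$combination["classifier"], x$mean_accuracy, length(x$folds),
              if (x$permuted) " (permuted labels)" else ""))
  invisible(x)
}

#' Results grid over extractor x selector x classifier combinations
#'
#' Runs [cross_validate()] for every combination; a failing cell is recorded
#' with `NA` accuracy and the error message, and the run continues.
#'
#' @param segments a `segment_set`.
#' @param extractors,selectors,classifiers character vectors of component
#'   names.
#' @param folds,seed,opts,cache passed to [cross_validate()].
#' @return An object of class `results_grid`: a long-format data frame of
#'   mean accuracies plus the per-cell `cv_result`s.
#' @export
results_grid <- function(segments, extractors = c("modwt", "kpca"),
                         selectors = c("ig", "btsa"),
                         classifiers = c("adaboost_mulda", "tw_hasvm"),
                         folds = 10L, seed = 1L, opts = list(), cache = NULL) {
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  cells <- expand.grid(extractor = extractors, selector = selectors,
                       classifier = classifiers, stringsAsFactors = FALSE)
  results <- vector("list", nrow(cells))
  acc <- rep(NA_real_, nrow(cells))
  err <- rep(NA_character_, nrow(cells))
  for (i in seq_len(nrow(cells))) {
    res <- tryCatch(
      cross_validate(segments, cells$extractor[i], cells$selector[i],
                     cells$classifier[i], folds, seed, opts, cache),
      error = function(e) e)
    if (inherits(res, "error")) {
      err[i] <- conditionMessage(res)
    } else {
      results[[i]] <- res
      acc[i] <- res$mean_accuracy
    }
  }
  grid <- cbind(cells, mean_accuracy = acc, error = err)
  best <- if (any(!is.na(acc))) grid[which.max(acc), , drop = FALSE] else NULL
  structure(list(grid = grid, results = results, best = best, seed = seed),
            class = "results_grid")
}

#' @export
print.results_grid <- function(x, ...) {
  cat("<results_grid>\n")
  for (sel in unique(x$grid$selector)) {
    sub <- x$grid[x$grid$selector == sel, ]
    wide <- stats::reshape(sub[, c("extractor", "classifier", "mean_accuracy")],
                           idvar = "extractor", timevar = "classifier",
                           direction = "wide")
    names(wide) <- sub("^mean_accuracy\\.", "", names(wide))
    cat(sprintf("-- selector: %s --\n", sel))
    print(wide, row.names = FALSE, digits = 4)
  }
  if (!is.null(x$best)) {
    cat(sprintf("best: %s + %s + %s (%.2f%%)\n", x$best$extractor,
                x$best$selector, x$best$classifier, x$best$mean_accuracy))
  }
  invisible(x)
}

#' Cohen's kappa
#'
#' Chance-corrected agreement between two label vectors.
#'
#' @param truth,pred factors or label vectors of equal length.
#' @return Kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(truth, pred) {
  truth <- factor(truth)
  pred <- factor(pred, levels = levels(truth))
  tab <- table(truth, pred)
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (pe == 1) return(1)
  (po - pe) / (1 - pe)
}

#' Feature statistics battery
#'
#' Per-feature Kruskal-Wallis and two-sided Wilcoxon rank-sum tests between
#' classes, a Friedman test across feature columns (rows as blocks), and
#' Cohen's kappa between a reference 10-NN classifier's cross-validated
#' predictions and the truth. All statistics are descriptive; none filters
#' features. Constant features are skipped with a note.
#'
#' @param table a [feature_table()] with both classes.
#' @param knn_k neighbour count of the reference classifier.
#' @param folds folds of the reference CV.
#' @param seed RNG seed.
#' @param p_adjust if `"BH"`, adds Benjamini-Hochberg adjusted columns
#'   (off by default).
#' @return A list with `per_feature` (data frame), `friedman`, `kappa`,
#'   `skipped`.
#' @export
feature_statistics <- function(table, knn_k = 10L, folds = 5L, seed = 1L,
                               p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  y <- table$labels
  if (nlevels(droplevels(y)) < 2L) stopf("need both classes present")
  X <- table$values
  skipped <- character()
  rows <- lapply(seq_len(ncol(X)), function(j) {
    x <- X[, j]
    if (stats::sd(x) == 0) {
      skipped <<- c(skipped, colnames(X)[j])
      return(data.frame(feature = colnames(X)[j], kw_stat = NA_real_,
                        kw_p = NA_real_, wilcox_stat = NA_real_,
                        wilcox_p = NA_real_))
    }
    kw <- stats::kruskal.test(x, y)
    wx <- suppressWarnings(stats::wilcox.test(x[y == "normal"],
                                              x[y == "hypertensive"],
                                              exact = FALSE))
    data.frame(feature = colnames(X)[j], kw_stat = unname(kw$statistic),
               kw_p = kw$p.value, wilcox_stat = unname(wx$statistic),
               wilcox_p = wx$p.value)
  })
  per_feature <- do.call(rbind, rows)
  if (p_adjust == "BH") {
    per_feature$kw_p_bh <- stats::p.adjust(per_feature$kw_p, "BH")
    per_feature$wilcox_p_bh <- stats::p.adjust(per_feature$wilcox_p, "BH")
  }
  fr <- if (ncol(X) >= 2L) stats::friedman.test(X) else NULL
  idx_folds <- stratified_folds(seq_len(nrow(X)), y, folds, derive_seed(seed, 7L))
  pred <- factor(rep(NA_character_, nrow(X)), levels = levels(y))
  for (fi in seq_along(idx_folds)) {
    test <- idx_folds[[fi]]
    train <- setdiff(seq_len(nrow(X)), test)
    pred[test] <- knn_predict(X[train, , drop = FALSE], X[test, , drop = FALSE],
                              y[train], knn_k, derive_seed(seed, 300L + fi))
  }
  list(per_feature = per_feature, friedman = fr,
       kappa = cohen_kappa(y, pred), skipped = skipped)
}
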