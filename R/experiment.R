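# End-to-end experiment runner: configuration schema, the synth-or-load ->
# preprocess -> grid pipeline, and fixture generation for examples and tests.

#' Experiment configuration
#'
#' Validated before any computation. The `"full"` profile keeps the reference
#' settings (10 folds, k-NN k = 10, linear KPCA with 4 components, wrapper
#' population 100 with 1000 generations, 1000 boosting rounds, batch 1);
#' the `"quick"` profile shrinks the iteration counts (population 20,
#' 20 generations, 20 boosting rounds) for desk-scale runs.
#'
#' @param data either a manifest path (`list(manifest = path)`) or a
#'   [synth_cohort_config()] for synthetic data.
#' @param ica apply [ica_clean()] to multi-channel records.
#' @param window_seconds segmentation window.
#' @param extractors,selectors,classifiers component names for the grid.
#' @param folds CV folds.
#' @param seed master RNG seed.
#' @param profile `"quick"` or `"full"`.
#' @param opts extra option overrides merged last (see [cross_validate()]).
#' @return A validated list of class `experiment_config`.
#' @export
experiment_config <- function(data = synth_cohort_config(),
                              ica = FALSE, window_seconds = 300,
                              extractors = c("modwt", "kpca"),
                              selectors = c("ig", "btsa"),
                              classifiers = c("adaboost_mulda", "tw_hasvm"),
                              folds = 10L, seed = 1L,
                              profile = c("quick", "full"), opts = list()) {
  profile <- match.arg(profile)
  bad <- setdiff(extractors, EXTRACTORS)
  if (length(bad)) stopf("unknown extractor(s) in field 'extractors': %s",
                         paste(bad, collapse = ", "))
  bad <- setdiff(selectors, SELECTORS)
  if (length(bad)) stopf("unknown selector(s) in field 'selectors': %s",
                         paste(bad, collapse = ", "))
  bad <- setdiff(classifiers, CLASSIFIERS)
  if (length(bad)) stopf("unknown classifier(s) in field 'classifiers': %s",
                         paste(bad, collapse = ", "))
  if (!is_count(folds, 2L)) stopf("folds must be a count >= 2")
  is_manifest <- is.list(data) && !is.null(data$manifest)
  if (!is_manifest && !inherits(data, "synth_cohort_config")) {
    stopf("data must be list(manifest = path) or a synth_cohort_config")
  }
  profile_opts <- if (profile == "quick") {
    list(selector_pop = 20L, selector_generations = 20L, boost_T = 20L,
         rf_trees = 20L)
  } else {
    list(selector_pop = 100L, selector_generations = 1000L, boost_T = 1000L,
         rf_trees = 100L)
  }
  structure(list(data = data, ica = ica, window_seconds = window_seconds,
                 extractors = extractors, selectors = selectors,
                 classifiers = classifiers, folds = as.integer(folds),
                 seed = as.integer(seed), profile = profile,
                 opts = utils::modifyList(profile_opts, opts)),
            class = "experiment_config")
}

#' Run a configured experiment end to end
#'
#' Generates or loads the cohort, optionally ICA-cleans, segments, evaluates
#' the full results grid, and persists the grid, the configuration and a
#' provenance record to `out_dir`.
#'
#' @param config an [experiment_config()].
#' @param out_dir output directory (created if needed); `NULL` skips writing.
#' @return The [results_grid()], invisibly.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  if (!inherits(config, "experiment_config")) stopf("config must be an experiment_config")
  cohort <- if (!is.null(config$data$manifest)) {
    read_cohort(config$data$manifest)
  } else {
    generate_bcg_cohort(config$data)
  }
  if (config$ica) {
    cohort <- structure(lapply(cohort, function(r) {
      if (length(r$channels) >= 2L) ica_clean(r, seed = config$seed) else r
    }), class = "bcg_cohort")
  }
  segments <- segment_cohort(cohort, config$window_seconds)
  grid <- results_grid(segments, config$extractors, config$selectors,
                       config$classifiers, config$folds, config$seed,
                       config$opts)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.csv(grid$grid, file.path(out_dir, "results_grid.csv"),
                     row.names = FALSE)
    prov <- list(config = rapply(unclass(config), unclass, how = "replace"),
                 timestamp = format(Sys.time(), tz = "UTC"),
                 r_version = R.version.string)
    jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  invisible(grid)
}

#' Write the fixture set used by examples and tests
#'
#' Writes a small synthetic cohort (manifest + waveforms), a labelled feature
#' table, a 3-feature brute-force toy table, the two-tone (5 Hz + 20 Hz)
#' signal and a simulated AR(1) series, all as plain text.
#'
#' @param out_dir writable output directory.
#' @param seed RNG seed.
#' @return Named list of written paths, invisibly.
#' @export
make_fixtures <- function(out_dir, seed = 1L) {
  if (!dir.exists(out_dir)) {
    ok <- tryCatch({ dir.create(out_dir, recursive = TRUE); TRUE },
                   warning = function(w) FALSE, error = function(e) FALSE)
    if (!ok || !dir.exists(out_dir)) stopf("cannot create directory %s", out_dir)
  }
  cohort <- generate_bcg_cohort(synth_cohort_config(
    n_normal = 3L, n_hyper = 3L, duration = 30, seed = seed))
  manifest <- write_cohort(cohort, file.path(out_dir, "cohort"))
  tab <- generate_feature_table(synth_table_config(n_samples = 60L, seed = seed))
  tab_path <- file.path(out_dir, "feature_table.csv")
  write_feature_table(tab, tab_path)
  toy <- generate_feature_table(synth_table_config(
    n_samples = 40L, d_informative = 1L, d_noise = 2L, effect_size = 3,
    seed = seed))
  toy_path <- file.path(out_dir, "toy_d3_table.csv")
  write_feature_table(toy, toy_path)
  t_grid <- (0:999) / 100
  twotone <- sin(2 * pi * 5 * t_grid) + sin(2 * pi * 20 * t_grid)
  twotone_path <- file.path(out_dir, "twotone_5_20hz.txt")
  utils::write.table(twotone, twotone_path, row.names = FALSE,
                     col.names = FALSE)
  ar1 <- with_local_seed(derive_seed(seed, 31L),
                         as.numeric(stats::arima.sim(list(ar = 0.7), 2000)))
  ar1_path <- file.path(out_dir, "ar1_phi07.txt")
  utils::write.table(ar1, ar1_path, row.names = FALSE, col.names = FALSE)
  invisible(list(manifest = manifest, feature_table = tab_path,
                 toy_d3 = toy_path, twotone = twotone_path, ar1 = ar1_path))
}
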