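# Synthetic two-class BCG cohorts and labelled feature tables with known
# ground truth, so every downstream stage is testable without external data.

#' Configuration for the synthetic BCG cohort generator
#'
#' Defaults mirror the acquisition conditions of the mattress-sensor cohort the
#' pipeline targets: 100 Hz sampling, 5-minute records, and class heart-rate
#' distributions of 73.6 +/- 8.3 bpm (normal) and 77.1 +/- 9.2 bpm
#' (hypertensive). The waveform contrast between classes (pulse amplitude and
#' width) is a controlled stand-in, not a physiological claim.
#'
#' @param n_normal,n_hyper subjects per class (>= 1).
#' @param fs sampling rate in Hz (> 0).
#' @param duration record length in seconds (> 0).
#' @param hr_mean_normal,hr_sd_normal,hr_mean_hyper,hr_sd_hyper class
#'   heart-rate distributions in bpm (SDs >= 0).
#' @param pulse_amp_ratio hypertensive/normal heartbeat-pulse amplitude ratio;
#'   1 means no morphological class contrast.
#' @param resp_freq respiratory baseline frequency in Hz.
#' @param noise_sd additive Gaussian sensor-noise SD (signal units; the
#'   normal-class pulse amplitude is 1).
#' @param seed integer RNG seed; the cohort is deterministic given the config.
#' @return A validated list of class `synth_cohort_config`.
#' @export
synth_cohort_config <- function(n_normal = 40L, n_hyper = 40L, fs = 100,
                                duration = 300, hr_mean_normal = 73.6,
                                hr_sd_normal = 8.3, hr_mean_hyper = 77.1,
                                hr_sd_hyper = 9.2, pulse_amp_ratio = 1.5,
                                resp_freq = 0.25, noise_sd = 0.1, seed = 1L) {
  if (!is_number(fs) || fs <= 0) stopf("fs must be a positive number")
  if (!is_number(duration) || duration <= 0) stopf("duration must be positive")
  if (!is_count(n_normal) || !is_count(n_hyper)) {
    stopf("n_normal and n_hyper must be counts >= 1")
  }
  if (!is_number(hr_sd_normal, 0) || !is_number(hr_sd_hyper, 0)) {
    stopf("heart-rate SDs must be >= 0")
  }
  if (!is_number(pulse_amp_ratio) || pulse_amp_ratio <= 0) {
    stopf("pulse_amp_ratio must be positive")
  }
  if (!is_number(noise_sd, 0)) stopf("noise_sd must be >= 0")
  structure(list(n_normal = as.integer(n_normal), n_hyper = as.integer(n_hyper),
                 fs = fs, duration = duration,
                 hr_mean_normal = hr_mean_normal, hr_sd_normal = hr_sd_normal,
                 hr_mean_hyper = hr_mean_hyper, hr_sd_hyper = hr_sd_hyper,
                 pulse_amp_ratio = pulse_amp_ratio, resp_freq = resp_freq,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synth_cohort_config")
}

# Per-class pulse morphology. The heartbeat complex is rendered as a
# Gaussian-windowed sinusoid (about three visible oscillations, an I-J-K-like
# complex); hypertensive pulses are scaled by pulse_amp_ratio in amplitude and
# narrowed by sqrt(pulse_amp_ratio) in width.
pulse_params <- function(label, pulse_amp_ratio) {
  base_amp <- 1
  base_width <- 0.12           # seconds; Gaussian SD of the window
  osc_freq <- 5                # Hz; carrier of the I-J-K oscillation
  if (label == "hypertensive") {
    list(amp = base_amp * pulse_amp_ratio,
         width = base_width / sqrt(pulse_amp_ratio), freq = osc_freq)
  } else {
    list(amp = base_amp, width = base_width, freq = osc_freq)
  }
}

# One subject's waveform: beats placed by a jittered inter-beat-interval
# process, each rendered with the class pulse template, plus sinusoidal
# respiratory drift and Gaussian sensor noise.
synth_record <- function(subject_id, label, hr_mean, hr_sd, config, seed) {
  fs <- config$fs
  n <- round(config$duration * fs)
  with_local_seed(seed, {
    hr <- min(max(stats::rnorm(1, hr_mean, hr_sd), 40), 140)
    ibi <- 60 / hr
    n_beats_max <- ceiling(config$duration / (0.3)) + 2L
    jitter <- stats::rnorm(n_beats_max, 0, 0.03)       # 3% per-beat IBI jitter
    ibis <- pmax(ibi * (1 + jitter), 0.3)
    beat_times <- cumsum(ibis)
    beat_times <- beat_times[beat_times < config$duration - 0.5]
    pp <- pulse_params(label, config$pulse_amp_ratio)
    x <- numeric(n)
    t_grid <- (seq_len(n) - 1) / fs
    half <- ceiling(3 * pp$width * fs)
    for (bt in beat_times) {
      i0 <- max(1L, floor((bt * fs)) - half)
      i1 <- min(n, floor((bt * fs)) + half)
      tt <- t_grid[i0:i1] - bt
      x[i0:i1] <- x[i0:i1] +
        pp$amp * exp(-0.5 * (tt / pp$width)^2) * sin(2 * pi * pp$freq * tt)
    }
    resp_phase <- stats::runif(1, 0, 2 * pi)
    x <- x + 0.3 * sin(2 * pi * config$resp_freq * t_grid + resp_phase)
    if (config$noise_sd > 0) x <- x + stats::rnorm(n, 0, config$noise_sd)
    structure(list(subject_id = subject_id, channels = list(x), fs = fs,
                   label = label,
                   demographics = list(hr = hr),
                   beat_times = beat_times),
              class = "bcg_record")
  })
}

#' Generate a synthetic two-class BCG cohort
#'
#' Each record contains `duration * fs` samples. Heartbeat events are placed by
#' an inter-beat-interval process drawn from the class heart-rate distribution
#' (3% per-beat jitter); each beat is a damped-oscillation pulse whose
#' amplitude and width differ between classes by `pulse_amp_ratio`; a
#' sinusoidal respiratory baseline and Gaussian sensor noise are added. The
#' whole cohort is deterministic given `config$seed`.
#'
#' @param config a [synth_cohort_config()].
#' @return A list of `bcg_record` objects, classed `bcg_cohort`.
#' @export
generate_bcg_cohort <- function(config) {
  if (!inherits(config, "synth_cohort_config")) config <- do.call(synth_cohort_config, config)
  recs <- vector("list", config$n_normal + config$n_hyper)
  k <- 0L
  for (i in seq_len(config$n_normal)) {
    k <- k + 1L
    recs[[k]] <- synth_record(sprintf("N%03d", i), "normal",
                              config$hr_mean_normal, config$hr_sd_normal,
                              config, derive_seed(config$seed, k))
  }
  for (i in seq_len(config$n_hyper)) {
    k <- k + 1L
    recs[[k]] <- synth_record(sprintf("H%03d", i), "hypertensive",
                              config$hr_mean_hyper, config$hr_sd_hyper,
                              config, derive_seed(config$seed, k))
  }
  structure(recs, class = "bcg_cohort", config = config)
}

#' @export
print.bcg_cohort <- function(x, ...) {
  labs <- vapply(x, function(r) r$label, "")
  cat(sprintf("<bcg_cohort> %d records (%d normal, %d hypertensive), fs = %g Hz\n",
              length(x), sum(labs == "normal"), sum(labs == "hypertensive"),
              x[[1]]$fs))
  invisible(x)
}

#' Configuration for the synthetic labelled feature table
#'
#' A balanced two-class Gaussian table with `d_informative` columns whose class
#' means differ by `effect_size` (in SD units) and `d_noise` class-independent
#' standard-normal columns. Informative columns are named `inf1..`, noise
#' columns `noise1..`, so selection tests have an exact ground truth.
#'
#' @param n_samples total rows (split evenly across the two classes).
#' @param d_informative number of informative columns (>= 1).
#' @param d_noise number of pure-noise columns (>= 0).
#' @param effect_size standardized class-mean shift on informative columns.
#' @param seed integer RNG seed.
#' @return A validated list of class `synth_table_config`.
#' @export
synth_table_config <- function(n_samples = 200L, d_informative = 5L,
                               d_noise = 15L, effect_size = 2, seed = 1L) {
  if (!is_count(d_informative)) stopf("d_informative must be a count >= 1")
  if (!is_count(d_noise, 0L)) stopf("d_noise must be a count >= 0")
  if (!is_number(effect_size, 0)) stopf("effect_size must be >= 0")
  if (!is_count(n_samples, 2L)) stopf("n_samples must be >= 2")
  structure(list(n_samples = as.integer(n_samples),
                 d_informative = as.integer(d_informative),
                 d_noise = as.integer(d_noise),
                 effect_size = effect_size, seed = as.integer(seed)),
            class = "synth_table_config")
}

#' Generate a synthetic labelled feature table
#'
#' @param config a [synth_table_config()].
#' @return A [feature_table()] with balanced binary labels.
#' @export
generate_feature_table <- function(config) {
  if (!inherits(config, "synth_table_config")) config <- do.call(synth_table_config, config)
  n <- config$n_samples
  n1 <- n %/% 2L
  labels <- c(rep("normal", n - n1), rep("hypertensive", n1))
  d <- config$d_informative + config$d_noise
  with_local_seed(config$seed, {
    values <- matrix(stats::rnorm(n * d), n, d)
    shift <- ifelse(labels == "hypertensive", config$effect_size, 0)
    for (j in seq_len(config$d_informative)) {
      values[, j] <- values[, j] + shift
    }
    nm <- c(paste0("inf", seq_len(config$d_informative)),
            if (config$d_noise > 0) paste0("noise", seq_len(config$d_noise)))
    feature_table(values, labels, nm,
                  provenance = list(extractor = "synthetic",
                                    config = unclass(config)))
  })
}
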