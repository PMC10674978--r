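# Synthetic cECG generation: PQRST-like beats (sums of Gaussian bumps),
# controllable RR statistics, baseline wander, additive noise and coarse
# motion artifacts, with per-sample ground truth.

#' Configuration for the synthetic cECG generator
#'
#' Bundles every knob of the generator. Defaults describe a reasonably clean
#' seat-electrode recording: 1 mV R peaks (capacitive couplings range from
#' roughly 0.1 to a few mV), 800 ms mean RR with 50 ms beat-to-beat
#' variability, mild wide-band noise, slow baseline wander and occasional
#' high-amplitude motion transients at ten times the R amplitude.
#'
#' @param fs Sampling frequency (Hz), > 0. Default 200.
#' @param duration_s Recording length in seconds, > 0.
#' @param r_amp_mv R-peak amplitude (mV).
#' @param rr_mean_ms,rr_sd_ms Mean and SD of the RR-interval distribution
#'   (ms). Intervals are truncated below at 250 ms.
#' @param noise_sd_mv SD of additive Gaussian noise (mV).
#' @param artifact_rate_per_min Expected number of coarse artifacts per
#'   minute (0 disables injection).
#' @param artifact_amp_mv Artifact amplitude (mV); default 10 x `r_amp_mv`,
#'   mimicking the very high amplitudes of motion transients relative to
#'   the useful signal.
#' @param artifact_dur_s Duration of each artifact (s).
#' @param drift_amp_mv,drift_freq_hz Amplitude (mV) and frequency (Hz) of a
#'   sinusoidal baseline wander.
#' @param seed Integer RNG seed, or NULL to use the current RNG stream.
#'
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(fs = 200, duration_s = 120, r_amp_mv = 1,
                         rr_mean_ms = 800, rr_sd_ms = 50,
                         noise_sd_mv = 0.02,
                         artifact_rate_per_min = 0,
                         artifact_amp_mv = 10 * r_amp_mv,
                         artifact_dur_s = 1,
                         drift_amp_mv = 0.1, drift_freq_hz = 0.1,
                         seed = NULL) {
  cfg <- list(
    fs = fs, duration_s = duration_s, r_amp_mv = r_amp_mv,
    rr_mean_ms = rr_mean_ms, rr_sd_ms = rr_sd_ms,
    noise_sd_mv = noise_sd_mv,
    artifact_rate_per_min = artifact_rate_per_min,
    artifact_amp_mv = artifact_amp_mv, artifact_dur_s = artifact_dur_s,
    drift_amp_mv = drift_amp_mv, drift_freq_hz = drift_freq_hz,
    seed = seed
  )
  stopifnot(
    fs > 0, duration_s > 0, rr_mean_ms > 0, rr_sd_ms >= 0,
    noise_sd_mv >= 0, artifact_rate_per_min >= 0, artifact_amp_mv >= 0,
    artifact_dur_s > 0, drift_amp_mv >= 0
  )
  class(cfg) <- "synth_config"
  cfg
}

#' Draw a reproducible RR-interval series
#'
#' Gaussian RR intervals truncated below at 250 ms (the refractory bound the
#' R-peak detector also enforces).
#'
#' @param n_beats Number of intervals to draw (>= 1).
#' @param rr_mean_ms Mean RR interval (ms), > 0.
#' @param rr_sd_ms SD of the RR interval (ms), >= 0.
#' @param seed Integer seed, or NULL for the current RNG stream.
#' @return Numeric vector of `n_beats` RR intervals in ms.
#' @examples
#' gen_rr_series(5, 1000, 0)
#' @export
gen_rr_series <- function(n_beats, rr_mean_ms, rr_sd_ms, seed = NULL) {
  if (!is.numeric(n_beats) || length(n_beats) != 1L || n_beats < 1) {
    stop("`n_beats` must be a positive count", call. = FALSE)
  }
  if (!is.numeric(rr_mean_ms) || rr_mean_ms <= 0) {
    stop("`rr_mean_ms` must be > 0", call. = FALSE)
  }
  if (rr_sd_ms < 0) stop("`rr_sd_ms` must be >= 0", call. = FALSE)
  with_seed_or_here(seed, {
    rr <- stats::rnorm(n_beats, rr_mean_ms, rr_sd_ms)
    pmax(rr, 250)
  })
}

# Beat template: five Gaussian bumps (P, Q, R, S, T). Offsets and widths are
# fractions of the local RR interval; amplitudes are fractions of the R
# amplitude. Widths are narrow enough that at the R sample the other bumps
# contribute < 1e-6 of the R amplitude, so the rendered maximum sits at the
# recorded R index by construction.
.beat_waves <- data.frame(
  wave   = c("P", "Q", "R", "S", "T"),
  offset = c(-0.200, -0.060, 0.000, 0.060, 0.280),
  width  = c(0.025, 0.012, 0.012, 0.012, 0.050),
  amp    = c(0.120, -0.080, 1.000, -0.150, 0.250)
)

#' Render an ECG trace from an RR series
#'
#' Each beat is a sum of five Gaussian bumps (P, Q, R, S, T) whose offsets
#' and widths scale with the local RR interval, so the only structure the
#' downstream pipeline relies on -- a dominant local maximum at R -- is
#' guaranteed. R bumps are centred exactly on a sample, and with zero noise
#' the rendered value at that sample equals `r_amp_mv` to ~1e-6 relative.
#'
#' @param rr_series Numeric vector of RR intervals (ms), non-empty.
#' @param fs Sampling frequency (Hz), >= 100 so the QRS is resolvable.
#' @param r_amp_mv R-peak amplitude (mV).
#' @param noise_sd_mv SD of additive Gaussian noise (mV).
#' @param seed Integer seed for the noise, or NULL.
#' @return A list with `signal` (a [cecg_signal]) and `truth`, a list with
#'   `r_peak_indices` (1-based sample positions of each R peak) and
#'   `artifact_mask` (all-FALSE logical, filled in by [inject_artifacts()]).
#' @export
render_ecg <- function(rr_series, fs, r_amp_mv = 1, noise_sd_mv = 0,
                       seed = NULL) {
  if (length(rr_series) < 1L || any(rr_series <= 0)) {
    stop("`rr_series` must be a non-empty vector of positive ms intervals",
      call. = FALSE)
  }
  if (fs < 100) {
    stop("`fs` must be >= 100 Hz to place the QRS template", call. = FALSE)
  }
  n_beats <- length(rr_series)
  rr_s <- rr_series / 1000
  # R-peak times: first R after a lead-in of 0.3 * RR1 (room for the P wave),
  # snapped to the sample grid so the maximum falls exactly on a sample.
  r_times <- 0.3 * rr_s[1] + cumsum(c(0, rr_s[-n_beats]))
  r_idx <- round(r_times * fs) + 1L
  n <- as.integer(ceiling((r_times[n_beats] + 0.6 * rr_s[n_beats]) * fs)) + 1L
  x <- numeric(n)
  t_idx <- (seq_len(n) - 1L) / fs
  for (b in seq_len(n_beats)) {
    rc <- (r_idx[b] - 1L) / fs   # grid-snapped R centre (s)
    rr_b <- rr_s[b]
    for (w in seq_len(nrow(.beat_waves))) {
      mu <- rc + .beat_waves$offset[w] * rr_b
      sg <- .beat_waves$width[w] * rr_b
      lo <- max(1L, as.integer(floor((mu - 5 * sg) * fs)) + 1L)
      hi <- min(n, as.integer(ceiling((mu + 5 * sg) * fs)) + 1L)
      if (lo > hi) next
      seg <- lo:hi
      x[seg] <- x[seg] +
        r_amp_mv * .beat_waves$amp[w] * exp(-((t_idx[seg] - mu)^2) / (2 * sg^2))
    }
  }
  if (noise_sd_mv > 0) {
    x <- x + with_seed_or_here(seed, stats::rnorm(n, 0, noise_sd_mv))
  }
  list(
    signal = cecg_signal(x, fs),
    truth = list(
      r_peak_indices = r_idx,
      artifact_mask = rep(FALSE, n),
      class_label = NA_character_
    )
  )
}

#' Inject coarse motion artifacts
#'
#' Overlays rectangular-plus-spike transients emulating the very
#' high-amplitude coarse artifacts produced by a moving subject. The number
#' of artifacts is `round(artifact_rate_per_min * duration / 60)`; starts
#' are drawn uniformly without overlap. The returned mask marks exactly the
#' modified samples; with zero artifacts the signal is returned unchanged.
#'
#' @param signal A [cecg_signal].
#' @param config A [synth_config] (fields `artifact_rate_per_min`,
#'   `artifact_amp_mv`, `artifact_dur_s` are used).
#' @param seed Integer seed, or NULL.
#' @return List with `signal` (artifacted copy) and `artifact_mask`
#'   (logical, same length).
#' @export
inject_artifacts <- function(signal, config, seed = NULL) {
  signal <- as_cecg_signal(signal)
  n <- length(signal$samples)
  fs <- signal$fs
  dur_s <- n / fs
  len <- as.integer(round(config$artifact_dur_s * fs))
  if (len > n) {
    stop("artifact duration exceeds signal duration", call. = FALSE)
  }
  n_art <- as.integer(round(config$artifact_rate_per_min * dur_s / 60))
  mask <- rep(FALSE, n)
  if (n_art == 0L || config$artifact_amp_mv == 0) {
    return(list(signal = signal, artifact_mask = mask))
  }
  x <- signal$samples
  with_seed_or_here(seed, {
    placed <- 0L
    tries <- 0L
    while (placed < n_art && tries < 200L * n_art) {
      tries <- tries + 1L
      start <- sample.int(n - len + 1L, 1L)
      span <- start:(start + len - 1L)
      if (any(mask[span])) next
      sgn <- sample(c(-1, 1), 1L)
      amp <- config$artifact_amp_mv
      # rectangular base with a sharper central spike (1.5x) on top
      art <- rep(amp, len)
      mid <- span[ceiling(len / 2)]
      spike <- max(1L, as.integer(round(0.05 * len)))
      spike_span <- max(start, mid - spike):min(start + len - 1L, mid + spike)
      art[spike_span - start + 1L] <- 1.5 * amp
      x[span] <- x[span] + sgn * art
      mask[span] <- TRUE
      placed <- placed + 1L
    }
    if (placed < n_art) {
      warning("could only place ", placed, " of ", n_art,
        " requested artifacts without overlap")
    }
  })
  list(signal = cecg_signal(x, fs, signal$meta), artifact_mask = mask)
}

#' Generate one labelled synthetic cECG recording
#'
#' Convenience wrapper chaining [gen_rr_series()], [render_ecg()], baseline
#' wander and [inject_artifacts()] according to one [synth_config].
#'
#' @param config A [synth_config].
#' @param seed Integer seed overriding `config$seed`, or NULL.
#' @param class_label Optional class label stored in the ground truth.
#' @return List with `signal` ([cecg_signal]) and `truth` (list:
#'   `r_peak_indices`, `artifact_mask`, `class_label`, plus
#'   `r_in_artifact`, flagging ground-truth R peaks overwritten by an
#'   artifact).
#' @export
gen_cecg <- function(config, seed = config$seed, class_label = NA_character_) {
  stopifnot(inherits(config, "synth_config"))
  with_seed_or_here(seed, {
    # 15% + 8 beats of margin so random RR draws cannot leave the render
    # shorter than the requested duration
    n_beats <- max(2L, as.integer(ceiling(
      config$duration_s * 1000 / config$rr_mean_ms * 1.15
    )) + 8L)
    rr <- gen_rr_series(n_beats, config$rr_mean_ms, config$rr_sd_ms)
    rend <- render_ecg(rr, config$fs, config$r_amp_mv, config$noise_sd_mv)
    x <- rend$signal$samples
    # trim/extend bookkeeping to the requested duration
    n <- min(length(x), as.integer(round(config$duration_s * config$fs)))
    x <- x[seq_len(n)]
    truth <- rend$truth
    keep <- truth$r_peak_indices <= n
    truth$r_peak_indices <- truth$r_peak_indices[keep]
    if (config$drift_amp_mv > 0) {
      tt <- (seq_len(n) - 1L) / config$fs
      phase <- stats::runif(1, 0, 2 * pi)
      x <- x + config$drift_amp_mv *
        sin(2 * pi * config$drift_freq_hz * tt + phase)
    }
    sig <- cecg_signal(x, config$fs)
    inj <- inject_artifacts(sig, config)
    truth$artifact_mask <- inj$artifact_mask
    truth$class_label <- class_label
    truth$r_in_artifact <- inj$artifact_mask[truth$r_peak_indices]
    list(signal = inj$signal, truth = truth)
  })
}

#' Default low/high stress generator configurations
#'
#' Higher stress is rendered as higher heart rate (shorter mean RR) with
#' reduced beat-to-beat variability, the direction in which both HR and
#' pNNx separate stress levels. Magnitudes are generator choices, not
#' empirical claims: 60 vs 80 bpm mean heart rate.
#'
#' @param fs Sampling frequency (Hz).
#' @param artifact_rate_per_min Coarse-artifact rate passed to both classes.
#' @return Named list with elements `low` and `high`, each a [synth_config].
#' @export
default_stress_configs <- function(fs = 200, artifact_rate_per_min = 1) {
  list(
    low = synth_config(
      fs = fs, duration_s = 50, rr_mean_ms = 1000, rr_sd_ms = 60,
      noise_sd_mv = 0.05, artifact_rate_per_min = artifact_rate_per_min
    ),
    high = synth_config(
      fs = fs, duration_s = 50, rr_mean_ms = 750, rr_sd_ms = 25,
      noise_sd_mv = 0.05, artifact_rate_per_min = artifact_rate_per_min
    )
  )
}

#' Generate a labelled two-class windowed dataset
#'
#' Produces `n_windows_per_class` 50-s windows per class, spread over
#' `n_subjects_per_class` synthetic subjects so subject-grouped
#' cross-validation splits are possible. Each subject receives a small
#' multiplicative jitter (1.5 % SD) on the mean RR to emulate
#' between-subject variation.
#'
#' @param config_low,config_high [synth_config]s for the low/high stress
#'   class; they should differ in `rr_mean_ms` and/or `rr_sd_ms`.
#' @param n_windows_per_class Windows per class (0 gives an empty dataset).
#' @param seed Integer seed, or NULL.
#' @param n_subjects_per_class Number of subjects per class (default 5).
#' @param window_s Window length in seconds (default 50).
#' @return A list of class `cecg_dataset`; each element has `signal`
#'   ([cecg_signal] of one window), `truth`, `label`
#'   (`"low_stress"`/`"high_stress"`), `subject` and `window_index`.
#' @export
gen_labeled_dataset <- function(config_low, config_high, n_windows_per_class,
                                seed = NULL, n_subjects_per_class = 5,
                                window_s = 50) {
  stopifnot(inherits(config_low, "synth_config"),
    inherits(config_high, "synth_config"))
  if (identical(config_low[c("rr_mean_ms", "rr_sd_ms")],
    config_high[c("rr_mean_ms", "rr_sd_ms")])) {
    warning("low and high configs have identical RR distributions; ",
      "classes are not separable by design")
  }
  out <- list()
  if (n_windows_per_class < 1) {
    return(structure(out, class = "cecg_dataset"))
  }
  with_seed_or_here(seed, {
    for (cls in c("low_stress", "high_stress")) {
      cfg <- if (cls == "low_stress") config_low else config_high
      n_sub <- max(1L, as.integer(n_subjects_per_class))
      per_sub <- diff(round(seq(0, n_windows_per_class, length.out = n_sub + 1)))
      for (s in seq_len(n_sub)) {
        if (per_sub[s] == 0L) next
        sub_id <- sprintf("%s_subj%02d", substr(cls, 1, 3), s)
        cfg_s <- cfg
        cfg_s$rr_mean_ms <- cfg$rr_mean_ms * exp(stats::rnorm(1, 0, 0.015))
        cfg_s$duration_s <- per_sub[s] * window_s
        rec <- gen_cecg(cfg_s, seed = NULL, class_label = cls)
        wlen <- as.integer(round(window_s * cfg_s$fs))
        for (w in seq_len(per_sub[s])) {
          span <- ((w - 1L) * wlen + 1L):(w * wlen)
          tr <- rec$truth
          in_w <- tr$r_peak_indices >= span[1] & tr$r_peak_indices <= span[length(span)]
          out[[length(out) + 1L]] <- list(
            signal = cecg_signal(rec$signal$samples[span], cfg_s$fs,
              meta = list(subject = sub_id, label = cls)),
            truth = list(
              r_peak_indices = tr$r_peak_indices[in_w] - span[1] + 1L,
              artifact_mask = tr$artifact_mask[span],
              class_label = cls
            ),
            label = cls, subject = sub_id, window_index = w
          )
        }
      }
    }
  })
  structure(out, class = "cecg_dataset")
}

#' @export
print.cecg_dataset <- function(x, ...) {
  labs <- vapply(x, `[[`, "", "label")
  cat(sprintf("<cecg_dataset> %d windows (%s)\n", length(x),
    paste(names(table(labs)), table(labs), sep = ": ", collapse = ", ")))
  invisible(x)
}

#' Write a dataset window and its ground truth to CSV
#'
#' Writes the two-column signal CSV (`time_s`, `amplitude_mv`) via
#' [write_signal()] plus a sidecar `<path>_truth.csv` with columns
#' `sample_index`, `is_artifact`, `is_rpeak`, `class`, `subject`.
#'
#' @param entry One element of a `cecg_dataset`.
#' @param path Output CSV path for the signal.
#' @return Invisibly, the two paths written.
#' @export
write_dataset_entry <- function(entry, path) {
  write_signal(entry$signal, path)
  truth_path <- sub("\\.csv$", "", path)
  truth_path <- paste0(truth_path, "_truth.csv")
  n <- length(entry$signal$samples)
  is_r <- rep(FALSE, n)
  is_r[entry$truth$r_peak_indices] <- TRUE
  utils::write.csv(
    data.frame(
      sample_index = seq_len(n),
      is_artifact = entry$truth$artifact_mask,
      is_rpeak = is_r,
      class = entry$label,
      subject = entry$subject
    ),
    truth_path,
    row.names = FALSE
  )
  invisible(c(path, truth_path))
}
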