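# R-peak detection and per-window feature extraction: R value, heart rate,
# pNNx and BinEn -- the only four features the classifier sees.

#' Detect R peaks
#'
#' Pan-Tompkins-family detector: band-limit the QRS energy with a
#' difference of moving averages, differentiate, square, integrate over a
#' 150 ms window, pick integrated peaks above an adaptive threshold, then
#' snap each candidate to the local maximum of the raw signal. Candidate
#' pairs closer than 250 ms (physiologically implausible RR) are merged,
#' keeping the larger peak.
#'
#' @param x A [cecg_signal] (>= 2 s of data recommended).
#' @param threshold_frac Fraction of the integrated-signal maximum used as
#'   detection threshold (default 0.2).
#' @param refractory_ms Minimum RR interval in ms (default 250).
#' @return An object of class `rpeak_series`: list with `indices` (1-based,
#'   strictly increasing), `amplitudes` (mV at those indices), `rri_ms`
#'   (successive differences in ms) and `fs`. A signal with no detectable
#'   beat yields an empty series, not an error.
#' @export
detect_rpeaks <- function(x, threshold_frac = 0.2, refractory_ms = 250) {
  x <- as_cecg_signal(x)
  v <- x$samples
  fs <- x$fs
  n <- length(v)
  empty <- structure(
    list(indices = integer(0), amplitudes = numeric(0),
      rri_ms = numeric(0), fs = fs),
    class = "rpeak_series"
  )
  if (n < 2 * fs) return(empty)

  ma <- function(z, w) {
    w <- max(1L, as.integer(w))
    as.numeric(stats::filter(z, rep(1 / w, w), sides = 2))
  }
  # crude 5-15 Hz band-limit: remove baseline (600 ms MA), smooth (40 ms MA)
  base <- ma(v, 0.6 * fs)
  band <- ma(v - ifelse(is.na(base), 0, base), 0.04 * fs)
  band[is.na(band)] <- 0
  d <- c(0, diff(band)) * fs
  integ <- ma(d^2, 0.15 * fs)
  integ[is.na(integ)] <- 0

  peak_max <- max(integ)
  if (!is.finite(peak_max) || peak_max <= 0 || stats::sd(v) == 0) {
    return(empty)
  }
  thr <- threshold_frac * peak_max
  above <- integ > thr
  if (!any(above)) return(empty)
  # contiguous supra-threshold runs -> one candidate each
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  cand <- integer(0)
  search <- as.integer(round(0.1 * fs))  # +-100 ms refinement window
  for (i in which(runs$values)) {
    lo <- max(1L, starts[i] - search)
    hi <- min(n, ends[i] + search)
    cand <- c(cand, lo - 1L + which.max(v[lo:hi]))
  }
  cand <- sort(unique(cand))
  # enforce refractory period: keep the larger of any too-close pair
  min_gap <- refractory_ms / 1000 * fs
  i <- 1L
  while (i < length(cand)) {
    if (cand[i + 1L] - cand[i] < min_gap) {
      drop <- if (v[cand[i]] >= v[cand[i + 1L]]) i + 1L else i
      cand <- cand[-drop]
    } else {
      i <- i + 1L
    }
  }
  structure(
    list(
      indices = cand,
      amplitudes = v[cand],
      rri_ms = diff(cand) / fs * 1000,
      fs = fs
    ),
    class = "rpeak_series"
  )
}

#' @export
print.rpeak_series <- function(x, ...) {
  cat(sprintf("<rpeak_series> %d peaks", length(x$indices)))
  if (length(x$rri_ms)) {
    cat(sprintf(", mean RR %.0f ms (HR %.1f bpm)",
      mean(x$rri_ms), mean(60000 / x$rri_ms)))
  }
  cat("\n")
  invisible(x)
}

#' Heart rate from RR intervals
#'
#' Instantaneous rate `HR = 60 / RRI[ms] * 1000` beats/min; a vector input
#' is summarised over the window, by default as the mean of instantaneous
#' rates (`method = "mean_rri"` instead returns `60000 / mean(RRI)`).
#'
#' @param rri_ms Positive RR interval(s) in ms.
#' @param method `"mean_hr"` (default) or `"mean_rri"`.
#' @return Heart rate in beats/min (scalar when `rri_ms` has length > 1).
#' @examples
#' heart_rate(1000) # 60
#' heart_rate(750)  # 80
#' @export
heart_rate <- function(rri_ms, method = c("mean_hr", "mean_rri")) {
  method <- match.arg(method)
  if (!is.numeric(rri_ms) || length(rri_ms) < 1L || any(rri_ms <= 0)) {
    stop("`rri_ms` must contain positive intervals (ms)", call. = FALSE)
  }
  if (length(rri_ms) == 1L) return(60 / rri_ms * 1000)
  switch(method,
    mean_hr = mean(60 / rri_ms * 1000),
    mean_rri = 60000 / mean(rri_ms)
  )
}

#' pNNx: fraction of large successive NN-interval differences
#'
#' Fraction of absolute successive differences of the normal-to-normal (NN)
#' interval series exceeding `x_ms` (50 ms by default, i.e. pNN50). NN
#' intervals are RR intervals after artifact reduction, so preprocessing is
#' an obligatory upstream step on real cECG.
#'
#' @param nn_ms NN interval series in ms, length >= 2.
#' @param x_ms Threshold in ms (default 50).
#' @return Fraction in `[0, 1]`, or `NA_real_` (undefined marker) when
#'   fewer than 2 intervals are supplied.
#' @examples
#' pnnx(c(800, 860, 870, 800)) # 2/3
#' @export
pnnx <- function(nn_ms, x_ms = 50) {
  if (length(nn_ms) < 2L) return(NA_real_)
  dn <- abs(diff(nn_ms))
  mean(dn > x_ms)
}

#' Per-window feature extraction
#'
#' Splits a (preprocessed) signal into `floor(duration / window_s)`
#' non-overlapping windows and computes the four features on each: mean
#' detected R amplitude (`r_value_mv`), heart rate (`hr_bpm`), `pnn50` and
#' `binen` on the window's raw samples. Windows with fewer than
#' `min_peaks` detected R peaks are dropped and counted, not errored.
#'
#' @param x A [cecg_signal] (typically the denoised output of
#'   [reduce_artifacts()]).
#' @param window_s Window length in seconds (default 50).
#' @param label,subject Carried into every row.
#' @param binen_par A [binen_params].
#' @param pnn_x_ms pNNx threshold in ms (default 50).
#' @param r_value_stat `"mean"` (default) or `"median"` R amplitude.
#' @param hr_method Passed to [heart_rate()].
#' @param min_peaks Minimum detected peaks per window (default 2).
#' @return A data.frame of class `cecg_features` with columns `subject`,
#'   `window_index`, `r_value_mv`, `hr_bpm`, `pnn50`, `binen`, `label`;
#'   attribute `dropped` records dropped windows and reasons.
#' @export
window_features <- function(x, window_s = 50, label = NA_character_,
                            subject = NA_character_,
                            binen_par = binen_params(),
                            pnn_x_ms = 50,
                            r_value_stat = c("mean", "median"),
                            hr_method = "mean_hr",
                            min_peaks = 2L) {
  x <- as_cecg_signal(x)
  r_value_stat <- match.arg(r_value_stat)
  wlen <- as.integer(round(window_s * x$fs))
  n_win <- length(x$samples) %/% wlen
  rows <- list()
  dropped <- data.frame(window_index = integer(0), reason = character(0))
  for (w in seq_len(n_win)) {
    span <- ((w - 1L) * wlen + 1L):(w * wlen)
    win <- cecg_signal(x$samples[span], x$fs)
    pk <- detect_rpeaks(win)
    if (length(pk$indices) < min_peaks) {
      dropped <- rbind(dropped,
        data.frame(window_index = w, reason = "too_few_peaks"))
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      subject = subject,
      window_index = w,
      r_value_mv = if (r_value_stat == "mean") mean(pk$amplitudes)
        else stats::median(pk$amplitudes),
      hr_bpm = heart_rate(pk$rri_ms, method = hr_method),
      pnn50 = pnnx(pk$rri_ms, pnn_x_ms),
      binen = binen(win$samples, binen_par),
      label = label,
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    subject = character(0), window_index = integer(0),
    r_value_mv = numeric(0), hr_bpm = numeric(0), pnn50 = numeric(0),
    binen = numeric(0), label = character(0)
  )
  attr(out, "dropped") <- dropped
  class(out) <- c("cecg_features", class(out))
  out
}

#' Feature table for a whole labelled dataset
#'
#' Runs [reduce_artifacts()] (optional) and [window_features()] on every
#' window of a `cecg_dataset` and stacks the rows.
#'
#' @param dataset A `cecg_dataset` from [gen_labeled_dataset()].
#' @param preprocess Run artifact reduction on each window first
#'   (default TRUE).
#' @param params A [preproc_params].
#' @param ... Passed to [window_features()].
#' @return A `cecg_features` data.frame.
#' @export
dataset_features <- function(dataset, preprocess = TRUE,
                             params = preproc_params(), ...) {
  stopifnot(inherits(dataset, "cecg_dataset"))
  rows <- lapply(seq_along(dataset), function(i) {
    e <- dataset[[i]]
    sig <- e$signal
    if (preprocess) {
      res <- reduce_artifacts(sig, params)
      if (res$empty_output) return(NULL)
      sig <- res$denoised
    }
    ft <- window_features(sig, window_s = length(sig$samples) / sig$fs,
      label = e$label, subject = e$subject, ...)
    if (nrow(ft)) ft$window_index <- e$window_index
    ft
  })
  rows <- Filter(function(r) !is.null(r) && nrow(r) > 0, rows)
  out <- if (length(rows)) do.call(rbind, rows) else
    window_features(cecg_signal(c(0, 0), 100), window_s = 1)[0, ]
  class(out) <- c("cecg_features", "data.frame")
  rownames(out) <- NULL
  out
}
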