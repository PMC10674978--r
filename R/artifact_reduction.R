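# Segment-wise elimination of coarse motion artifacts and slow-changing
# artifacts in cECG, driven by detrended-fluctuation statistics of the
# centralized cumulative-sum profile.

#' Preprocessing parameters
#'
#' @param SL Segment length in samples (>= 4). `NA` (default) means "use one
#'   second of samples", resolved against the signal's sampling rate inside
#'   [reduce_artifacts()]; a 1-s segment is comparable to one cardiac cycle,
#'   so a coarse transient dominates its segment.
#' @param C Dimensionless constant in `[0.15, 0.35]` (interpreted per mV^2);
#'   default 0.25, the midpoint of the admissible range.
#' @param C1 Normalising constant, 1 mV.
#' @param TH3 Slow-artifact threshold on the per-segment fluctuation,
#'   default 0.1.
#' @param poly_order Detrending polynomial order; only linear (`1`) is
#'   supported.
#' @return A validated list of class `preproc_params`.
#' @export
preproc_params <- function(SL = NA, C = 0.25, C1 = 1, TH3 = 0.1,
                           poly_order = 1) {
  if (!is.na(SL) && SL < 4) stop("`SL` must be >= 4 samples", call. = FALSE)
  if (C < 0.15 || C > 0.35) {
    stop("`C` must lie in [0.15, 0.35]", call. = FALSE)
  }
  if (poly_order != 1) {
    stop("only linear detrending (`poly_order = 1`) is supported",
      call. = FALSE)
  }
  structure(
    list(SL = SL, C = C, C1 = C1, TH3 = TH3, poly_order = 1L),
    class = "preproc_params"
  )
}

#' Centralized cumulative-sum profile
#'
#' `Y(i) = sum_{k<=i} (x_k - mean(x))`. The last element is zero up to
#' floating-point error by the telescoping identity.
#'
#' @param x A [cecg_signal] or numeric vector.
#' @return Numeric vector of the same length as the input.
#' @examples
#' centralized_cumsum(c(1, 2, 3)) # -1 -1 0
#' @export
centralized_cumsum <- function(x) {
  v <- if (inherits(x, "cecg_signal")) x$samples else x
  if (!is.numeric(v) || length(v) < 1L) {
    stop("input must be a non-empty numeric vector or cecg_signal",
      call. = FALSE)
  }
  cumsum(v - mean(v))
}

#' Per-segment detrended fluctuation
#'
#' Splits the profile `Y` into `floor(N / SL)` non-overlapping segments of
#' length `SL` (trailing remainder discarded) and returns, for each, the
#' mean squared residual around its own linear least-squares fit.
#'
#' @param Y Numeric profile, usually from [centralized_cumsum()].
#' @param SL Segment length in samples, `4 <= SL <= length(Y)`.
#' @return Numeric vector of `floor(length(Y)/SL)` non-negative values.
#' @export
segment_fd <- function(Y, SL) {
  if (SL > length(Y)) {
    stop("`SL` exceeds the profile length", call. = FALSE)
  }
  if (SL < 2) stop("`SL` must be >= 2", call. = FALSE)
  n_seg <- length(Y) %/% SL
  if (n_seg < 1L) stop("no complete segment fits", call. = FALSE)
  # closed-form linear fit per segment on the common abscissa k = 1..SL
  k <- seq_len(SL)
  k_c <- k - mean(k)
  skk <- sum(k_c^2)
  seg <- matrix(Y[seq_len(n_seg * SL)], nrow = SL)
  mu <- colMeans(seg)
  slope <- as.numeric(crossprod(k_c, seg)) / skk
  resid <- seg - rep(mu, each = SL) - outer(k_c, slope)
  colSums(resid^2) / SL
}

#' Coarse-artifact presence check
#'
#' Declares coarse artifacts present when
#' `(max(x) - min(x)) / 2 - M > 1` with `M = mean(x^2)` (second moment,
#' mV^2). Amplitudes must be in mV; the constant 1 is treated as numeric
#' under that convention.
#'
#' @param x A [cecg_signal] or numeric vector (mV).
#' @return Logical scalar.
#' @export
coarse_present <- function(x) {
  v <- if (inherits(x, "cecg_signal")) x$samples else x
  m2 <- mean(v^2)
  (max(v) - min(v)) / 2 - m2 > 1
}

#' Coarse-artifact elimination threshold TH1
#'
#' `TH1 = (((max(x)-min(x))/2)^2 - M) * C * (median(FD) + SD(FD) + SD(x)) /
#' (SD(FD) * SD(x) * C1)`, all amplitudes in mV. The grouping is kept in
#' this single function so an alternative reading is a one-line change.
#'
#' @param x A [cecg_signal] or numeric vector (mV).
#' @param FD Per-segment fluctuation values from [segment_fd()], length >= 2.
#' @param params A [preproc_params].
#' @return Finite numeric threshold.
#' @export
compute_th1 <- function(x, FD, params = preproc_params()) {
  v <- if (inherits(x, "cecg_signal")) x$samples else x
  if (length(FD) < 2L) stop("need >= 2 segments to compute TH1", call. = FALSE)
  sd_fd <- stats::sd(FD)
  sd_x <- stats::sd(v)
  if (sd_fd == 0 || sd_x == 0) {
    stop("degenerate input: constant signal or constant FD (zero SD)",
      call. = FALSE)
  }
  m2 <- mean(v^2)
  half_range <- (max(v) - min(v)) / 2
  (half_range^2 - m2) * params$C *
    (stats::median(FD) + sd_fd + sd_x) / (sd_fd * sd_x * params$C1)
}

#' Segment-wise artifact reduction
#'
#' Full elimination procedure:
#' \enumerate{
#'   \item Compute the centralized cumulative-sum profile and per-segment
#'     fluctuations `FD_j` (segments of `SL` samples).
#'   \item If [coarse_present()] is `TRUE`, eliminate segments with
#'     `FD_j > TH1` (reason `"coarse"`), then eliminate any neighbour of an
#'     eliminated segment whose fluctuation differs from it by more than
#'     `TH2 = TH1 / 2` (reason `"adjacent"` -- coarse artifacts spill over
#'     into adjacent segments). If `FALSE`, coarse elimination is skipped
#'     entirely.
#'   \item Slow-changing artifacts: only when `mean(FD) - SD(FD) > TH3`,
#'     eliminate segments with `FD_j < TH3` (reason `"slow"`). Such
#'     segments carry almost no fluctuation around their linear trend,
#'     i.e. they are baseline drift with no cardiac content; the gate
#'     protects genuinely low-intensity recordings, whose fluctuation
#'     level is globally small, from being cut.
#' }
#' The denoised signal is the concatenation of kept segments (the time axis
#' is rescaled). When nothing is eliminated the input is returned
#' unmodified, including any trailing part-segment, so clean signals pass
#' through bit-identically.
#'
#' @param x A [cecg_signal].
#' @param params A [preproc_params]; `SL = NA` resolves to `round(fs)`.
#' @return A list of class `segmentation_result`:
#'   \describe{
#'     \item{FD}{per-segment fluctuation values}
#'     \item{M, TH1, TH2}{second moment and thresholds (TH1/TH2 are `NA`
#'       when the coarse branch was not entered)}
#'     \item{keep_mask}{logical per segment}
#'     \item{reason}{`"kept"`, `"coarse"`, `"adjacent"` or `"slow"`}
#'     \item{kept_sample_index_map}{original indices of retained samples}
#'     \item{denoised}{the concatenated [cecg_signal] (`NULL` when
#'       everything was eliminated, flagged by `empty_output`)}
#'     \item{empty_output}{TRUE when all segments were eliminated}
#'   }
#' @export
reduce_artifacts <- function(x, params = preproc_params()) {
  x <- as_cecg_signal(x)
  SL <- if (is.na(params$SL)) as.integer(round(x$fs)) else as.integer(params$SL)
  n <- length(x$samples)
  if (n < 2L * SL) {
    stop("signal shorter than two segments (", 2L * SL, " samples)",
      call. = FALSE)
  }
  Y <- centralized_cumsum(x)
  FD <- segment_fd(Y, SL)
  n_seg <- length(FD)
  m2 <- mean(x$samples^2)
  keep <- rep(TRUE, n_seg)
  reason <- rep("kept", n_seg)
  th1 <- NA_real_
  th2 <- NA_real_

  if (coarse_present(x)) {
    th1 <- compute_th1(x, FD, params)
    th2 <- th1 / 2
    coarse <- FD > th1
    keep[coarse] <- FALSE
    reason[coarse] <- "coarse"
    # spill-over: neighbours of coarse segments with a large FD jump
    adj <- rep(FALSE, n_seg)
    for (j in which(coarse)) {
      for (nb in c(j - 1L, j + 1L)) {
        if (nb >= 1L && nb <= n_seg && keep[nb] &&
          abs(FD[j] - FD[nb]) > th2) {
          adj[nb] <- TRUE
        }
      }
    }
    keep[adj] <- FALSE
    reason[adj] <- "adjacent"
  }

  if (mean(FD) - stats::sd(FD) > params$TH3) {
    slow <- keep & (FD < params$TH3)
    keep[slow] <- FALSE
    reason[slow] <- "slow"
  }

  if (all(keep)) {
    idx_map <- seq_len(n)   # untouched, trailing remainder included
    denoised <- x
    empty <- FALSE
  } else if (!any(keep)) {
    idx_map <- integer(0)
    denoised <- NULL
    empty <- TRUE
  } else {
    seg_starts <- (which(keep) - 1L) * SL
    idx_map <- as.integer(outer(seq_len(SL), seg_starts, `+`))
    denoised <- cecg_signal(x$samples[idx_map], x$fs,
      meta = c(x$meta, list(denoised = TRUE)))
    empty <- FALSE
  }

  structure(
    list(
      FD = FD, M = m2, TH1 = th1, TH2 = th2, SL = SL,
      keep_mask = keep, reason = reason,
      kept_sample_index_map = idx_map,
      denoised = denoised, empty_output = empty
    ),
    class = "segmentation_result"
  )
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf(
    "<segmentation_result> %d segments of %d samples; kept %d (%.1f%%)\n",
    length(x$FD), x$SL, sum(x$keep_mask),
    100 * mean(x$keep_mask)
  ))
  tab <- table(x$reason[!x$keep_mask])
  if (length(tab)) {
    cat("  eliminated:", paste(names(tab), tab, sep = "=", collapse = ", "),
      "\n")
  }
  if (x$empty_output) cat("  WARNING: all segments eliminated\n")
  invisible(x)
}

#' Write a per-segment elimination report
#'
#' @param result A `segmentation_result` from [reduce_artifacts()].
#' @param path Output CSV path.
#' @return Invisibly, the data frame written (columns `segment_index`,
#'   `FD`, `eliminated`, `reason`).
#' @export
write_segment_report <- function(result, path) {
  df <- data.frame(
    segment_index = seq_along(result$FD),
    FD = result$FD,
    eliminated = !result$keep_mask,
    reason = ifelse(result$keep_mask, "", result$reason)
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
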