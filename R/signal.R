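#' Single-channel cECG signal container
#'
#' Lightweight container for a uniformly sampled capacitive-ECG (or ordinary
#' ECG) trace. Amplitudes are stored in millivolt throughout the package;
#' readers convert on load.
#'
#' @param samples Numeric vector of amplitudes (mV), length >= 2.
#' @param fs Sampling frequency in Hz, a single positive number.
#' @param meta Optional named list of free-form provenance (subject id,
#'   class label, source file, ...).
#'
#' @return An object of class `cecg_signal`: a list with elements
#'   `samples`, `fs` and `meta`.
#' @examples
#' sig <- cecg_signal(sin(seq(0, 2 * pi, length.out = 200)), fs = 100)
#' sig
#' @export
cecg_signal <- function(samples, fs, meta = list()) {
  if (!is.numeric(samples) || length(samples) < 2L) {
    stop("`samples` must be a numeric vector of length >= 2", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a single positive number (Hz)", call. = FALSE)
  }
  if (anyNA(samples)) stop("`samples` must not contain NA", call. = FALSE)
  structure(
    list(samples = as.numeric(samples), fs = as.numeric(fs), meta = meta),
    class = "cecg_signal"
  )
}

#' @export
print.cecg_signal <- function(x, ...) {
  dur <- length(x$samples) / x$fs
  cat(sprintf(
    "<cecg_signal> %d samples @ %g Hz (%.1f s), range [%.3g, %.3g] mV\n",
    length(x$samples), x$fs, dur, min(x$samples), max(x$samples)
  ))
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
      sep = "=", collapse = ", "
    ), "\n")
  }
  invisible(x)
}

#' @export
length.cecg_signal <- function(x) length(x$samples)

# Internal: coerce numeric vector / cecg_signal to cecg_signal.
as_cecg_signal <- function(x, fs = NULL) {
  if (inherits(x, "cecg_signal")) return(x)
  if (is.null(fs)) stop("`fs` required when `x` is a bare numeric vector",
    call. = FALSE)
  cecg_signal(x, fs)
}

# Internal: run `expr` under `seed` without disturbing the caller's RNG
# stream; seed = NULL uses the current stream.
with_seed_or_here <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}
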