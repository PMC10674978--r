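# Independent oracles used across the suite. These deliberately take the
# naive route (explicit window enumeration, lm() fits, elementwise loops)
# so they share no code path with the package implementation.

# O(N^2) pairwise-matching estimator of the BinEn Phi summand: enumerate
# every embedding window, compare all pairs elementwise (self-matches
# included), average the log match fractions.
naive_window_matrix <- function(c, m, tau = 1) {
  W <- length(c) - (m - 1L) * tau
  stopifnot(W >= 1L)
  vapply(seq_len(W), function(i) c[i + (0:(m - 1L)) * tau], integer(m)) |>
    matrix(nrow = m)
}

naive_hamming_pairs <- function(win) {
  m <- nrow(win)
  D <- matrix(0L, ncol(win), ncol(win))
  for (l in seq_len(m)) {
    D <- D + outer(win[l, ], win[l, ], `!=`)
  }
  D
}

naive_phi <- function(c, m, r, tau = 1) {
  D <- naive_hamming_pairs(naive_window_matrix(c, m, tau))
  mean(log(rowMeans(D <= r)))
}

naive_binen <- function(x, m, r, tau = 1) {
  c <- as.integer(diff(x) > 0)
  naive_phi(c, m, r, tau) - naive_phi(c, m + 1L, r, tau)
}

# Brute-force per-segment detrended fluctuation via lm() (QR least squares,
# a different algorithm from the package's closed-form normal equations).
lm_segment_fd <- function(Y, SL) {
  n_seg <- length(Y) %/% SL
  vapply(seq_len(n_seg), function(j) {
    seg <- Y[((j - 1) * SL + 1):(j * SL)]
    k <- seq_len(SL)
    mean(stats::residuals(stats::lm(seg ~ k))^2)
  }, 0)
}

# Minimal WFDB writers for round-trip tests (formats 16 and 212).
write_wfdb_record <- function(dir, name, channels_mv, fs, fmt = "16",
                              gain = 200, descs = NULL) {
  n_sig <- length(channels_mv)
  n <- length(channels_mv[[1]])
  if (is.null(descs)) descs <- paste0("ch", seq_len(n_sig))
  adc <- lapply(channels_mv, function(x) as.integer(round(x * gain)))
  inter <- as.integer(do.call(rbind, adc))  # sample-interleaved
  dat <- paste0(name, ".dat")
  if (fmt == "16") {
    writeBin(inter, file.path(dir, dat), size = 2L, endian = "little")
  } else if (fmt == "212") {
    if (length(inter) %% 2L) inter <- c(inter, 0L)
    u <- ifelse(inter < 0L, inter + 4096L, inter)
    s1 <- u[seq(1, length(u), by = 2)]
    s2 <- u[seq(2, length(u), by = 2)]
    bytes <- as.raw(rbind(
      bitwAnd(s1, 0xFF),
      bitwOr(bitwShiftR(s1, 8L), bitwShiftL(bitwAnd(bitwShiftR(s2, 8L), 0x0F), 4L)),
      bitwAnd(s2, 0xFF)
    ))
    writeBin(bytes, file.path(dir, dat))
  } else {
    stop("unsupported fmt")
  }
  hea <- c(
    sprintf("%s %d %g %d", name, n_sig, fs, n),
    sprintf("%s %s %d(0)/mV 12 0 0 0 0 %s", dat, fmt, gain, descs)
  )
  writeLines(hea, file.path(dir, paste0(name, ".hea")))
  file.path(dir, name)
}

# Shared quick fixture: a clean rendered ECG.
clean_ecg <- function(n_beats = 60, rr = 1000, fs = 200, amp = 1,
                      noise = 0, seed = 42) {
  render_ecg(rep(rr, n_beats), fs = fs, r_amp_mv = amp,
    noise_sd_mv = noise, seed = seed)
}
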