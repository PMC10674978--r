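# Binarized approximate entropy (BinEn): approximate entropy computed on
# the sign sequence of first differences, in linear time via counts of
# binary embedding vectors and a 2^m x 2^m Hamming-distance matrix.

#' BinEn parameters
#'
#' @param m Embedding size, 1--4 recommended. Default 2.
#' @param tau Embedding delay, >= 1. Default 1.
#' @param r Hamming-distance tolerance in `0..m`. Default 0 (exact match),
#'   the natural choice for binary symbols; it makes BinEn a
#'   conditional-entropy-rate estimate of the difference-sign process.
#' @return Validated list of class `binen_params`.
#' @export
binen_params <- function(m = 2, tau = 1, r = 0) {
  if (m < 1) stop("`m` must be >= 1", call. = FALSE)
  if (tau < 1) stop("`tau` must be >= 1", call. = FALSE)
  if (r < 0 || r > m) stop("`r` must lie in 0..m", call. = FALSE)
  structure(list(m = as.integer(m), tau = as.integer(tau), r = as.integer(r)),
    class = "binen_params")
}

#' Binary differential encoding
#'
#' `c_i = 1` if `x_{i+1} - x_i > 0`, else `0` (ties code to 0).
#'
#' @param x Numeric vector, length >= 2.
#' @return Integer 0/1 vector of length `length(x) - 1`.
#' @examples
#' binary_diff_encode(c(1, 3, 2, 2)) # 1 0 0
#' @export
binary_diff_encode <- function(x) {
  if (!is.numeric(x) || length(x) < 2L) {
    stop("`x` must be numeric with length >= 2", call. = FALSE)
  }
  as.integer(diff(x) > 0)
}

#' Decimal code of one binary embedding vector
#'
#' `k = sum_{n=0}^{m-1} c[1 + n] * 2^n`: the first element is the
#' least-significant bit.
#'
#' @param c_window Binary vector of exactly `m` symbols (already taken with
#'   the desired delay).
#' @return Integer in `0 .. 2^m - 1`.
#' @examples
#' vector_decimal(c(1, 0, 1)) # 5
#' @export
vector_decimal <- function(c_window) {
  m <- length(c_window)
  if (m < 1L || !all(c_window %in% c(0L, 1L))) {
    stop("`c_window` must be a non-empty 0/1 vector", call. = FALSE)
  }
  as.integer(sum(c_window * 2^(seq_len(m) - 1L)))
}

# Internal: decimal codes of all embedding windows of c (vectorized).
window_codes <- function(c, m, tau) {
  n_win <- length(c) - (m - 1L) * tau
  if (n_win < 1L) {
    stop("sequence too short for m = ", m, ", tau = ", tau, call. = FALSE)
  }
  k <- integer(n_win)
  for (n in 0:(m - 1L)) {
    k <- k + c[(1L + n * tau):(n_win + n * tau)] * 2L^n
  }
  k
}

#' Counts and empirical pmf of binary embedding vectors
#'
#' Counts each of the `2^m` possible vectors over the
#' `length(c) - (m - 1) * tau` embedding windows and normalizes to a
#' probability mass function.
#'
#' @param c Integer 0/1 sequence.
#' @param m Embedding size.
#' @param tau Embedding delay.
#' @return List with `counts` (length `2^m`, names = decimal codes
#'   `0..2^m-1`), `pmf` and `n_windows`.
#' @export
vector_counts <- function(c, m, tau = 1) {
  k <- window_codes(as.integer(c), as.integer(m), as.integer(tau))
  counts <- tabulate(k + 1L, nbins = 2L^m)
  names(counts) <- 0:(2L^m - 1L)
  list(counts = counts, pmf = counts / length(k), n_windows = length(k))
}

#' Hamming-distance matrix between all m-bit codes
#'
#' Entry `(k, n)` (0-based codes) is `popcount(k XOR n)`: the number of
#' differing bits between the vectors with decimal codes `k` and `n`.
#'
#' @param m Number of bits.
#' @return Symmetric `2^m x 2^m` integer matrix with zero diagonal and
#'   entries in `0..m`.
#' @export
hamming_matrix <- function(m) {
  if (m < 1) stop("`m` must be >= 1", call. = FALSE)
  codes <- 0:(2L^m - 1L)
  xor <- outer(codes, codes, bitwXor)
  H <- matrix(0L, length(codes), length(codes))
  for (b in 0:(m - 1L)) {
    H <- H + bitwAnd(bitwShiftR(xor, b), 1L)
  }
  dimnames(H) <- list(codes, codes)
  H
}

#' The Phi summand of BinEn
#'
#' For every code `k`, `p_hat_k = sum_n pmf(n) * I(hamming(k, n) <= r)` is
#' the probability that a random embedding vector lies within Hamming
#' distance `r` of the vector coded `k`; then
#' `Phi = sum_k pmf(k) * ln(p_hat_k)`. Self-matches are always included
#' (`hamming(k, k) = 0 <= r`), so the logarithm is defined for every
#' occurring vector and `Phi <= 0`.
#'
#' @param c Integer 0/1 sequence.
#' @param m Embedding size.
#' @param r Hamming tolerance, `0..m`.
#' @param tau Embedding delay.
#' @return Scalar `Phi` (nats), <= 0.
#' @export
binen_phi <- function(c, m, r = 0, tau = 1) {
  if (r < 0 || r > m) stop("`r` must lie in 0..m", call. = FALSE)
  vc <- vector_counts(c, m, tau)
  within_r <- hamming_matrix(m) <= r
  p_hat <- as.numeric(within_r %*% vc$pmf)
  occ <- vc$pmf > 0
  sum(vc$pmf[occ] * log(p_hat[occ]))
}

#' Binarized approximate entropy
#'
#' `BinEn = Phi(m) - Phi(m + 1)`, both orders computed with the same delay
#' and tolerance on the binary difference-sign sequence of `x`. Only the
#' signs of successive differences enter, so the statistic is invariant to
#' any strictly increasing transform of `x`. Constant or strictly monotone
#' inputs give exactly 0.
#'
#' @param x Numeric signal (raw samples, not RR intervals), length
#'   `>= m * tau + 2` so both orders are computable.
#' @param params A [binen_params] (or use `m`, `tau`, `r` directly).
#' @param m,tau,r Convenience scalar overrides of `params`.
#' @return Entropy estimate in nats, >= 0 up to floating error.
#' @examples
#' binen(cumsum(rnorm(500)))
#' @export
binen <- function(x, params = binen_params(m = m, tau = tau, r = r),
                  m = 2, tau = 1, r = 0) {
  if (inherits(x, "cecg_signal")) x <- x$samples
  m <- params$m; tau <- params$tau; r <- params$r
  if (length(x) < m * tau + 2L) {
    stop("`x` too short: need length >= m*tau + 2 = ", m * tau + 2L,
      call. = FALSE)
  }
  c <- binary_diff_encode(x)
  binen_phi(c, m, r, tau) - binen_phi(c, m + 1L, r, tau)
}
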