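#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

check_finite <- function(x, what = "input") {
  if (!all(is.finite(Re(x))) || (is.complex(x) && !all(is.finite(Im(x)))))
    stop_config("%s contains non-finite values", what)
  invisible(TRUE)
}

#' Moore-Penrose pseudoinverse
#'
#' SVD-based pseudoinverse for real or complex matrices; singular values
#' below `tol * max(sv)` are treated as zero.
#'
#' @param x matrix (real or complex).
#' @param tol relative singular-value cutoff.
#' @return matrix with `ncol(x)` rows and `nrow(x)` columns.
#' @keywords internal
pinv <- function(x, tol = 1e-12) {
  s <- svd(x)
  keep <- s$d > tol * max(s$d, 0)
  if (!any(keep)) return(matrix(0 + 0i * x[1], ncol(x), nrow(x)))
  s$v[, keep, drop = FALSE] %*%
    (Conj(t(s$u[, keep, drop = FALSE])) / s$d[keep])
}

# Hermitian / symmetric clean-up after round-trips through products.
hermitize <- function(x) (x + Conj(t(x))) / 2
symmetrize <- function(x) (x + t(x)) / 2

# Frobenius norm valid for complex matrices (base norm() coerces)
fnorm <- function(x) sqrt(sum(Mod(x)^2))

#' Zero-phase FFT band-pass filter
#'
#' Brick-wall frequency-domain filter with raised-cosine edges, applied
#' symmetrically so the result has exactly zero phase distortion. Used both
#' by the synthetic generator (band-limited noise shaping) and as the
#' independent narrowband oracle that MEMD band reconstructions are checked
#' against.
#'
#' @param x numeric vector, or channel x sample matrix (filtered row-wise).
#' @param fs sampling rate in Hz.
#' @param lo,hi pass-band edges in Hz; `0 < lo < hi <= fs/2`.
#' @param taper_hz width of the raised-cosine transition band, Hz.
#' @return filtered signal, same shape as `x`.
#' @export
bandpass_fft <- function(x, fs, lo, hi, taper_hz = 1) {
  if (lo <= 0 || hi <= lo || hi > fs / 2)
    stop_config("band edges must satisfy 0 < lo < hi <= fs/2")
  if (is.matrix(x)) {
    return(t(apply(x, 1L, bandpass_fft, fs = fs, lo = lo, hi = hi,
                   taper_hz = taper_hz)))
  }
  n <- length(x)
  f <- c(seq_len(ceiling(n / 2) + 1L) - 1L,
         if (n > 1) -(rev(seq_len(n - ceiling(n / 2) - 1L)))) * fs / n
  f <- abs(f[seq_len(n)])
  gain <- rep(0, n)
  inband <- f >= lo & f <= hi
  gain[inband] <- 1
  if (taper_hz > 0) {
    lo_edge <- f >= lo - taper_hz & f < lo
    hi_edge <- f > hi & f <= hi + taper_hz
    gain[lo_edge] <- 0.5 * (1 + cos(pi * (lo - f[lo_edge]) / taper_hz))
    gain[hi_edge] <- 0.5 * (1 + cos(pi * (f[hi_edge] - hi) / taper_hz))
  }
  Re(stats::fft(stats::fft(x) * gain, inverse = TRUE)) / n
}

# Radical-inverse (van der Corput) digits of i in the given base.
radical_inverse <- function(i, base) {
  r <- 0
  f <- 1 / base
  while (i > 0) {
    r <- r + f * (i %% base)
    i <- i %/% base
    f <- f / base
  }
  r
}

first_primes <- function(k) {
  primes <- integer(0)
  n <- 2L
  while (length(primes) < k) {
    if (all(n %% primes[primes <= sqrt(n)] != 0)) primes <- c(primes, n)
    n <- n + 1L
  }
  primes
}

#' Low-discrepancy direction vectors on the unit hypersphere
#'
#' Hammersley-sequence points mapped through the Gaussian quantile so that
#' normalised rows are close to uniformly spread on the sphere. Deterministic.
#'
#' @param n number of directions.
#' @param dim ambient dimension (number of channels).
#' @return `n x dim` matrix of unit row vectors.
#' @keywords internal
hammersley_sphere <- function(n, dim) {
  stopifnot(n >= 1, dim >= 1)
  u <- matrix(0, n, dim)
  u[, 1L] <- (seq_len(n) - 0.5) / n
  if (dim > 1) {
    bases <- first_primes(dim - 1L)
    for (j in seq_len(dim - 1L))
      u[, j + 1L] <- vapply(seq_len(n), radical_inverse, 0, base = bases[j])
  }
  # keep quantiles strictly inside (0,1)
  u[u <= 0] <- 0.5 / n
  g <- stats::qnorm(u)
  g / sqrt(rowSums(g^2))
}

# standard error of the mean
sem <- function(x) stats::sd(x) / sqrt(length(x))
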