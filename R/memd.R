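#' Sifting configuration for multivariate EMD
#'
#' @param n_directions number of projection directions on the unit
#'   hypersphere (low-discrepancy Hammersley set); must be at least twice
#'   the channel count.
#' @param max_imfs cap on the number of extracted modes.
#' @param stop_thresholds Rilling-style triple `c(theta1, theta2, alpha)`:
#'   sifting stops when the normalized mean-envelope amplitude is below
#'   `theta1` on at least a fraction `1 - alpha` of samples and below
#'   `theta2` everywhere.
#' @param max_sift_iters hard cap on sifting iterations per mode.
#' @param envelope_interp interpolation scheme; natural cubic splines only.
#' @param boundary extrema boundary rule; mirror extension only.
#' @return a `sift_config`.
#' @export
sift_config <- function(n_directions = 64L, max_imfs = 11L,
                        stop_thresholds = c(0.05, 0.5, 0.05),
                        max_sift_iters = 100L,
                        envelope_interp = "cubic_spline",
                        boundary = "mirror") {
  stopifnot(length(stop_thresholds) == 3L, all(stop_thresholds > 0))
  envelope_interp <- match.arg(envelope_interp, "cubic_spline")
  boundary <- match.arg(boundary, "mirror")
  structure(list(n_directions = as.integer(n_directions),
                 max_imfs = as.integer(max_imfs),
                 stop_thresholds = stop_thresholds,
                 max_sift_iters = as.integer(max_sift_iters),
                 envelope_interp = envelope_interp, boundary = boundary),
            class = "sift_config")
}

# local extrema of a series; strictly alternating plateaus collapse to midpoints
local_extrema <- function(p) {
  n <- length(p)
  d <- diff(p)
  nz <- which(d != 0)
  if (length(nz) < 2L) return(list(max = integer(0), min = integer(0)))
  # compress plateaus: compare consecutive distinct slopes
  s <- sign(d[nz])
  chg <- which(s[-1] != s[-length(s)])
  if (!length(chg)) return(list(max = integer(0), min = integer(0)))
  idx <- vapply(chg, function(k) {
    # extremum between end of run k and start of run k+1 (plateau midpoint)
    lo <- nz[k] + 1L
    hi <- nz[k + 1L]
    as.integer((lo + hi) %/% 2L)
  }, 0L)
  is_max <- s[chg] > 0
  list(max = idx[is_max], min = idx[!is_max])
}

# mirror boundary extension (2 extrema reflected about each endpoint);
# interior extrema are guaranteed to lie in [2, n-1], so knots stay distinct
mirror_extrema <- function(idx, n) {
  k <- min(2L, length(idx))
  left <- 2L - idx[k:1]            # ascending positions < 1
  right <- 2L * n - rev(idx)[1:k]  # ascending positions > n
  list(x = c(left, idx, right), k = k)
}

# multivariate envelope through extrema of one projection (h: channel x sample)
proj_envelope <- function(h, idx, n) {
  ext <- mirror_extrema(idx, n)
  k <- ext$k
  env <- matrix(0, nrow(h), n)
  for (ch in seq_len(nrow(h))) {
    y <- h[ch, idx]
    yext <- c(y[k:1], y, rev(y)[1:k])  # mirrored knots reuse reflected values
    env[ch, ] <- stats::spline(ext$x, yext, xout = seq_len(n),
                               method = "natural")$y
  }
  env
}

# one evaluation of the multivariate mean envelope and sift-stop statistics
mean_envelope <- function(h, dirs) {
  n <- ncol(h)
  m <- matrix(0, nrow(h), n)
  amp <- numeric(n)
  n_used <- 0L
  tot_extrema <- 0L
  for (d in seq_len(nrow(dirs))) {
    p <- as.numeric(dirs[d, ] %*% h)
    ex <- local_extrema(p)
    tot_extrema <- tot_extrema + length(ex$max) + length(ex$min)
    if (length(ex$max) < 2L || length(ex$min) < 2L) next
    env_max <- proj_envelope(h, ex$max, n)
    env_min <- proj_envelope(h, ex$min, n)
    m <- m + (env_max + env_min) / 2
    amp <- amp + sqrt(colSums((env_max - env_min)^2)) / 2
    n_used <- n_used + 1L
  }
  if (n_used > 0L) {
    m <- m / n_used
    amp <- amp / n_used
  }
  list(m = m, amp = amp, n_used = n_used, tot_extrema = tot_extrema)
}

#' Multivariate empirical mode decomposition
#'
#' Projects the multichannel signal onto `n_directions` unit vectors,
#' interpolates channel-space envelopes through each projection's extrema,
#' and sifts against the direction-averaged mean envelope. All channels
#' share one set of aligned modes (the property that motivates MEMD over
#' channel-wise EMD), and the modes plus residue reconstruct the input to
#' floating-point accuracy.
#'
#' @param x `channel x sample` numeric matrix (at least 2 channels,
#'   64 samples).
#' @param cfg a [sift_config()].
#' @param fs sampling rate stored in the result (metadata only).
#' @return an `imf_set`: list with `imfs` (`mode x channel x sample` array),
#'   `residue` (`channel x sample`), `fs`, `n_channels`.
#' @export
memd_decompose <- function(x, cfg = sift_config(), fs = NA_real_) {
  if (!is.matrix(x)) stop_config("x must be a channel x sample matrix")
  if (nrow(x) < 2L) stop_config("MEMD needs at least 2 channels")
  if (ncol(x) < 64L) stop_config("MEMD needs at least 64 samples")
  check_finite(x, "MEMD input")
  if (cfg$n_directions < 2L * nrow(x))
    stop_config("n_directions (%d) must be >= 2 * channel count (%d)",
                cfg$n_directions, 2L * nrow(x))
  dirs <- hammersley_sphere(cfg$n_directions, nrow(x))
  th1 <- cfg$stop_thresholds[1L]
  th2 <- cfg$stop_thresholds[2L]
  alpha <- cfg$stop_thresholds[3L]

  r <- x
  imfs <- list()
  for (k in seq_len(cfg$max_imfs)) {
    probe <- mean_envelope(r, dirs)
    # no usable extrema left: residue is (near) monotone on all projections
    if (probe$n_used == 0L || probe$tot_extrema < 3L * nrow(dirs)) break
    h <- r
    me <- probe
    for (it in seq_len(cfg$max_sift_iters)) {
      if (me$n_used == 0L) break
      h_new <- h - me$m
      sx <- sqrt(colSums(me$m^2)) / pmax(me$amp, .Machine$double.eps)
      stop_ok <- (mean(sx > th1) <= alpha) && all(sx < th2)
      h <- h_new
      if (stop_ok) break
      me <- mean_envelope(h, dirs)
    }
    imfs[[k]] <- h
    r <- r - h
  }
  n_modes <- length(imfs)
  imf_arr <- array(0, c(n_modes, nrow(x), ncol(x)))
  for (k in seq_len(n_modes)) imf_arr[k, , ] <- imfs[[k]]
  structure(list(imfs = imf_arr, residue = r, fs = fs,
                 n_channels = nrow(x)),
            class = "imf_set")
}

#' @export
print.imf_set <- function(x, ...) {
  cat(sprintf("IMF set: %d modes, %d channels, %d samples\n",
              dim(x$imfs)[1L], dim(x$imfs)[2L], dim(x$imfs)[3L]))
  invisible(x)
}

#' Noise-assisted MEMD
#'
#' Appends `n_noise_channels` white Gaussian noise channels before sifting
#' (stabilizing the dyadic mode separation) and discards the noise
#' channels' modes from the result, which therefore has exactly the
#' original channel count.
#'
#' @inheritParams memd_decompose
#' @param noise_sd standard deviation of the assisting noise; must be
#'   positive. `NULL` uses 2% of the average channel standard deviation.
#' @param n_noise_channels number of appended noise channels.
#' @param seed integer seed controlling the noise (decomposition is
#'   deterministic given the seed).
#' @return an `imf_set` with the original channels only.
#' @export
na_memd_decompose <- function(x, cfg = sift_config(), noise_sd = NULL,
                              n_noise_channels = 1L, seed = 1L,
                              fs = NA_real_) {
  if (is.null(noise_sd)) noise_sd <- 0.02 * mean(apply(x, 1L, stats::sd))
  if (!is.numeric(noise_sd) || noise_sd <= 0)
    stop_config("noise_sd must be > 0 (a zero-noise sift is degenerate)")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))
  noise <- matrix(stats::rnorm(n_noise_channels * ncol(x), 0, noise_sd),
                  n_noise_channels, ncol(x))
  if (cfg$n_directions < 2L * (nrow(x) + n_noise_channels))
    cfg$n_directions <- 2L * (nrow(x) + n_noise_channels)
  dec <- memd_decompose(rbind(x, noise), cfg, fs = fs)
  keep <- seq_len(nrow(x))
  dec$imfs <- dec$imfs[, keep, , drop = FALSE]
  dec$residue <- dec$residue[keep, , drop = FALSE]
  dec$n_channels <- nrow(x)
  dec
}

#' Bartlett-window periodogram
#'
#' Power spectral estimate using a triangular (Bartlett) data window; when
#' the series is longer than `window_len` it is cut into non-overlapping
#' segments whose periodograms are averaged. Power is scaled so that the
#' spectral sum equals the windowed-signal variance (Parseval).
#'
#' @param series numeric vector.
#' @param nfft FFT length (>= `window_len`; series segments are
#'   zero-padded).
#' @param window_len window size in samples.
#' @param fs sampling rate, Hz.
#' @return list with `freqs` (Hz, `0 .. fs/2`) and `power` (nonnegative).
#' @export
periodogram_bartlett <- function(series, nfft = 640L, window_len = 640L, fs) {
  if (nfft < window_len) stop_config("nfft must be >= window_len")
  if (window_len > length(series))
    stop_config("window_len (%d) exceeds series length (%d)",
                window_len, length(series))
  n_seg <- length(series) %/% window_len
  w <- bartlett_window(window_len)
  acc <- numeric(nfft)
  for (s in seq_len(n_seg)) {
    seg <- series[((s - 1L) * window_len + 1L):(s * window_len)]
    y <- (seg - mean(seg)) * w
    acc <- acc + Mod(stats::fft(c(y, numeric(nfft - window_len))))^2
  }
  two_sided <- acc / (n_seg * nfft * window_len)
  half <- nfft %/% 2L
  power <- two_sided[1:(half + 1L)]
  # fold negative-frequency bins (Nyquist bin has no mirror when nfft even)
  mirror <- if (nfft %% 2L == 0L) seq_len(half - 1L) + 1L else seq_len(half) + 1L
  if (length(mirror)) power[mirror] <- power[mirror] + two_sided[nfft - mirror + 2L]
  list(freqs = (0:half) * fs / nfft, power = power)
}

bartlett_window <- function(n) {
  k <- seq_len(n) - 1L
  1 - abs((k - (n - 1) / 2) / ((n - 1) / 2))
}

# mode x frequency spectrum table averaged over channels (and trials)
imf_population_spectra <- function(imfsets, nfft = NULL, fs = NULL) {
  if (inherits(imfsets, "imf_set")) imfsets <- list(imfsets)
  n_modes <- min(vapply(imfsets, function(s) dim(s$imfs)[1L], 0L))
  fs <- fs %||% imfsets[[1L]]$fs
  n_samp <- dim(imfsets[[1L]]$imfs)[3L]
  nfft <- nfft %||% n_samp
  power <- NULL
  freqs <- NULL
  for (k in seq_len(n_modes)) {
    acc <- NULL
    cnt <- 0L
    for (s in imfsets) {
      for (ch in seq_len(dim(s$imfs)[2L])) {
        pg <- periodogram_bartlett(s$imfs[k, ch, ], nfft = nfft,
                                   window_len = min(nfft, n_samp), fs = fs)
        acc <- if (is.null(acc)) pg$power else acc + pg$power
        freqs <- pg$freqs
        cnt <- cnt + 1L
      }
    }
    row <- acc / cnt
    power <- rbind(power, row)
  }
  list(freqs = freqs, power = unname(power), window = "bartlett", nfft = nfft)
}

#' Assign IMFs to the mu and beta rhythms
#'
#' `fixed` policy returns the canonical assignment observed on 160 Hz
#' motor-imagery recordings: mode 4 carries the mu rhythm and modes 2 + 3
#' the beta rhythm. `auto` averages Bartlett spectra over the supplied
#' decompositions (all channels, all trials) and assigns each mode to
#' whichever band — mu, beta, or neither — holds the largest fraction of
#' its average power.
#'
#' @param imfsets one `imf_set` or a list of them (a population to average
#'   over).
#' @param mu_band,beta_band band edges in Hz.
#' @param policy `"fixed"` or `"auto"`.
#' @param fs sampling rate; taken from the IMF sets when `NULL`.
#' @return list with integer vectors `mu_modes`, `beta_modes` and, for the
#'   auto policy, the averaged `spectra` used for the decision.
#' @export
select_rhythm_imfs <- function(imfsets, mu_band = c(8, 13),
                               beta_band = c(13, 25),
                               policy = c("fixed", "auto"), fs = NULL) {
  policy <- match.arg(policy)
  if (inherits(imfsets, "imf_set")) imfsets <- list(imfsets)
  n_modes <- min(vapply(imfsets, function(s) dim(s$imfs)[1L], 0L))
  if (policy == "fixed") {
    if (n_modes < 4L)
      stop_config("fixed policy needs >= 4 shared modes (have %d)", n_modes)
    return(list(mu_modes = 4L, beta_modes = c(2L, 3L)))
  }
  sp <- imf_population_spectra(imfsets, fs = fs)
  in_band <- function(band) sp$freqs > band[1L] & sp$freqs <= band[2L]
  mu_modes <- integer(0); beta_modes <- integer(0)
  for (k in seq_len(n_modes)) {
    tot <- sum(sp$power[k, ])
    if (tot <= 0) next
    f_mu <- sum(sp$power[k, in_band(mu_band)]) / tot
    f_beta <- sum(sp$power[k, in_band(beta_band)]) / tot
    f_out <- 1 - f_mu - f_beta
    best <- which.max(c(f_mu, f_beta, f_out))
    if (best == 1L) mu_modes <- c(mu_modes, k)
    if (best == 2L) beta_modes <- c(beta_modes, k)
  }
  if (!length(mu_modes) || !length(beta_modes)) {
    stop(structure(class = c("rhythm_selection_error", "error", "condition"),
                   list(message = "auto rhythm selection found an empty band; inspect $spectra",
                        call = sys.call(-1L), spectra = sp)))
  }
  list(mu_modes = mu_modes, beta_modes = beta_modes, spectra = sp)
}

#' Partial reconstruction from selected modes
#'
#' Sums the chosen IMFs; with all modes selected the result plus residue
#' equals the decomposed input exactly.
#'
#' @param imfset an `imf_set`.
#' @param modes integer mode indices (possibly empty).
#' @return `channel x sample` matrix.
#' @export
reconstruct_band <- function(imfset, modes) {
  d <- dim(imfset$imfs)
  out <- matrix(0, d[2L], d[3L])
  if (!length(modes)) return(out)
  modes <- as.integer(modes)
  if (any(modes < 1L | modes > d[1L])) stop_config("mode index out of range")
  for (k in modes) out <- out + imfset$imfs[k, , ]
  out
}

# zero-crossing count per mode (averaged over channels); used for the
# quasi-dyadic ordering diagnostics
imf_zero_crossings <- function(imfset) {
  d <- dim(imfset$imfs)
  vapply(seq_len(d[1L]), function(k) {
    mean(vapply(seq_len(d[2L]), function(ch) {
      x <- imfset$imfs[k, ch, ]
      sum(diff(sign(x[x != 0])) != 0)
    }, 0))
  }, 0)
}
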