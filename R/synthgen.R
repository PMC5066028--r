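#' Labeled multichannel EEG trial set
#'
#' The common currency of every pipeline stage: a `trial x channel x sample`
#' numeric array with per-trial class labels ("L" = left-hand imagery,
#' "R" = right-hand imagery), channel names and a sampling rate.
#'
#' @param data numeric array, `n_trials x n_channels x n_samples`.
#' @param labels character/factor of length `n_trials`, values "L"/"R".
#' @param channel_names length-`n_channels` character vector.
#' @param fs sampling rate, Hz.
#' @return an `eeg_trial_set`.
#' @export
eeg_trial_set <- function(data, labels, channel_names, fs) {
  if (length(dim(data)) != 3L)
    stop_config("data must be a trial x channel x sample array")
  labels <- as.character(labels)
  if (length(labels) != dim(data)[1L])
    stop_config("labels length (%d) != trial count (%d)",
                length(labels), dim(data)[1L])
  if (!all(labels %in% c("L", "R")))
    stop_config("labels must be 'L' or 'R'")
  if (length(channel_names) != dim(data)[2L])
    stop_config("channel_names length != channel count")
  check_finite(data, "trial data")
  structure(list(data = data, labels = labels,
                 channel_names = as.character(channel_names), fs = fs),
            class = "eeg_trial_set")
}

#' @export
print.eeg_trial_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("EEG trial set: %d trials (%d L / %d R), %d channels, %d samples @ %g Hz\n",
              d[1L], sum(x$labels == "L"), sum(x$labels == "R"),
              d[2L], d[3L], x$fs))
  invisible(x)
}

n_trials <- function(x) dim(x$data)[1L]

#' Narrowband source specification
#'
#' One rhythm-band source per hemisphere. Amplitudes are given per class and
#' per hemisphere as `c(left_hemisphere, right_hemisphere)` root-mean-square
#' values, so class-dependent lateralization (event-related
#' desynchronization being stronger contralaterally) is expressed directly.
#'
#' @param band_low,band_high pass-band edges in Hz.
#' @param amp_left_class,amp_right_class length-2 nonnegative numerics:
#'   RMS amplitude on the (left, right) hemisphere during left-class and
#'   right-class trials respectively.
#' @param waveform `"bandlimited_noise"` (band-pass filtered Gaussian noise,
#'   the default) or `"amplitude_modulated_sinusoid"`.
#' @param name label used in ground-truth tables.
#' @return a `source_spec`.
#' @export
source_spec <- function(band_low, band_high, amp_left_class, amp_right_class,
                        waveform = c("bandlimited_noise",
                                     "amplitude_modulated_sinusoid"),
                        name = sprintf("%g-%gHz", band_low, band_high)) {
  waveform <- match.arg(waveform)
  if (!(band_low > 0 && band_low < band_high))
    stop_config("need 0 < band_low < band_high")
  if (length(amp_left_class) != 2L || length(amp_right_class) != 2L ||
      any(c(amp_left_class, amp_right_class) < 0))
    stop_config("class amplitudes must be nonnegative pairs (left, right hemisphere)")
  structure(list(band_low = band_low, band_high = band_high,
                 amp_left_class = amp_left_class,
                 amp_right_class = amp_right_class,
                 waveform = waveform, name = name),
            class = "source_spec")
}

#' Default mu/beta sources with contralateral desynchronization
#'
#' Mu (8-13 Hz) and beta (13-25 Hz) sources whose hemisphere amplitudes drop
#' contralaterally to the imagined hand, the textbook ERD pattern. All three
#' CSP variants separate this configuration.
#'
#' @return list of two `source_spec`s.
#' @export
default_sources <- function() {
  list(
    mu = source_spec(8, 13, amp_left_class = c(1.0, 0.45),
                     amp_right_class = c(0.45, 1.0), name = "mu"),
    beta = source_spec(13, 25, amp_left_class = c(0.8, 0.35),
                       amp_right_class = c(0.35, 0.8), name = "beta")
  )
}

#' Synthetic dataset configuration
#'
#' Defaults mirror the target recording setup: 160 Hz sampling, 640-sample
#' (4 s) trials, a 14-channel whole-scalp montage. The physical model has
#' two spatial sources — a left and a right sensorimotor patch — each
#' emitting one independent narrowband signal per rhythm band, so the
#' mixing matrix has one column per patch (shared by mu and beta, as for a
#' cortical generator producing both rhythms). When `mixing` is `NULL` a
#' montage-driven full-column-rank matrix is built: ipsilateral weight 1,
#' contralateral 0.15, midline `sqrt(0.5)` from each hemisphere (so midline
#' power is the average of the two hemispheres).
#'
#' @param fs sampling rate, Hz.
#' @param n_samples samples per trial.
#' @param n_trials_per_class trials per class.
#' @param sources list of [source_spec()]s.
#' @param montage a [montage_config()]; defines channels and hemispheres.
#' @param mixing optional `channel x 2` matrix with one column per spatial
#'   source (left patch, right patch).
#' @param noise_sd standard deviation of additive broadband sensor noise.
#' @param amp_jitter_sd sdlog of the per-trial, per-source log-normal
#'   amplitude jitter (0 disables).
#' @param seed integer RNG seed; identical seeds give bit-identical data.
#' @return a `synth_config`.
#' @export
synth_config <- function(fs = 160, n_samples = 640, n_trials_per_class = 50,
                         sources = default_sources(),
                         montage = default_montage(),
                         mixing = NULL, noise_sd = 0.5, amp_jitter_sd = 0.1,
                         seed = 1L) {
  for (s in sources) {
    if (s$band_high >= fs / 2)
      stop_config("source band %s exceeds Nyquist", s$name)
    if (n_samples < 2 * fs / s$band_low)
      stop_config("n_samples too small for slowest band (%g Hz): need >= %g",
                  s$band_low, 2 * fs / s$band_low)
  }
  n_ch <- length(montage$channel_names)
  if (is.null(mixing)) mixing <- build_mixing(montage)
  if (nrow(mixing) != n_ch || ncol(mixing) != 2L)
    stop_config("mixing must be %d x 2 (left patch, right patch)", n_ch)
  if (qr(mixing)$rank < ncol(mixing))
    stop_config("mixing matrix is rank-deficient")
  structure(list(fs = fs, n_samples = n_samples,
                 n_trials_per_class = n_trials_per_class,
                 sources = sources, montage = montage, mixing = mixing,
                 noise_sd = noise_sd, amp_jitter_sd = amp_jitter_sd,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# montage-driven mixing: one column per spatial source (hemisphere patch)
build_mixing <- function(montage) {
  hemi <- montage_hemisphere(montage)
  n_ch <- length(hemi)
  base <- function(h_col) {
    w <- numeric(n_ch)
    w[hemi == h_col] <- 1
    w[hemi == -h_col] <- 0.15
    w[hemi == 0] <- sqrt(0.5)
    w
  }
  m <- cbind(left = base(1), right = base(-1))
  rownames(m) <- montage$channel_names
  m
}

# one unit-RMS narrowband realization
narrowband_signal <- function(spec, n, fs) {
  if (spec$waveform == "bandlimited_noise") {
    w <- stats::rnorm(2L * n)
    taper <- min(1, (spec$band_high - spec$band_low) / 4)
    y <- bandpass_fft(w, fs, spec$band_low, spec$band_high, taper_hz = taper)
    y <- y[(n %/% 2 + 1L):(n %/% 2 + n)]  # discard filter wrap-around edges
  } else {
    f0 <- stats::runif(1L, spec$band_low, spec$band_high)
    ph <- stats::runif(2L, 0, 2 * pi)
    fm <- stats::runif(1L, 0.3, 1)
    t <- seq_len(n) / fs
    y <- sin(2 * pi * f0 * t + ph[1L]) * (1 + 0.5 * sin(2 * pi * fm * t + ph[2L]))
  }
  y / stats::sd(y)
}

#' Generate a synthetic motor-imagery dataset
#'
#' Draws `2 * n_trials_per_class` trials (classes interleaved L, R, L, R, ...)
#' of hemisphere-lateralized narrowband sources mixed linearly to channels
#' with additive broadband Gaussian noise. Ground truth — mixing matrix,
#' per-trial source amplitudes and realized band powers, and the per-band
#' channel-space component signals — is returned alongside the data, never
#' hidden in state.
#'
#' @param config a [synth_config()].
#' @return list with elements `trials` (an [eeg_trial_set()]) and `truth`
#'   (list: `mixing`, `source_names`, `amplitudes` trial x source matrix,
#'   `band_powers` trial x source matrix of realized channel-averaged band
#'   powers, and `components`, a named list of trial x channel x sample
#'   arrays, one per source spec, holding that band's noiseless
#'   channel-space contribution).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  n_tr <- 2L * config$n_trials_per_class
  n_ch <- length(config$montage$channel_names)
  n_s <- config$n_samples
  labels <- rep_len(c("L", "R"), n_tr)
  specs <- config$sources
  n_src <- length(specs)
  src_names <- vapply(seq_along(specs), function(i) {
    nm <- specs[[i]]$name %||% paste0("src", i)
    nm
  }, "")
  col_names <- as.vector(t(outer(src_names, c("left", "right"), paste, sep = ".")))

  data <- array(0, c(n_tr, n_ch, n_s))
  components <- lapply(specs, function(s) array(0, c(n_tr, n_ch, n_s)))
  names(components) <- src_names
  amplitudes <- matrix(0, n_tr, 2L * n_src, dimnames = list(NULL, col_names))
  band_powers <- matrix(0, n_tr, n_src, dimnames = list(NULL, src_names))

  for (tr in seq_len(n_tr)) {
    cls <- labels[tr]
    for (si in seq_len(n_src)) {
      spec <- specs[[si]]
      amps <- if (cls == "L") spec$amp_left_class else spec$amp_right_class
      comp <- matrix(0, n_ch, n_s)
      for (h in 1:2) {  # 1 = left hemisphere patch, 2 = right
        jit <- if (config$amp_jitter_sd > 0)
          stats::rlnorm(1L, 0, config$amp_jitter_sd) else 1
        a <- amps[h] * jit
        amplitudes[tr, 2L * (si - 1L) + h] <- a
        sig <- a * narrowband_signal(spec, n_s, config$fs)
        comp <- comp + config$mixing[, h] %o% sig
      }
      components[[si]][tr, , ] <- comp
      band_powers[tr, si] <- mean(comp^2)
      data[tr, , ] <- data[tr, , ] + comp
    }
    if (config$noise_sd > 0)
      data[tr, , ] <- data[tr, , ] +
        matrix(stats::rnorm(n_ch * n_s, 0, config$noise_sd), n_ch, n_s)
  }
  list(
    trials = eeg_trial_set(data, labels, config$montage$channel_names, config$fs),
    truth = list(mixing = config$mixing, source_names = src_names,
                 amplitudes = amplitudes, band_powers = band_powers,
                 components = components),
    config = config
  )
}

#' Difference-only configuration
#'
#' Rewrites a base configuration (one mu and one beta source) so that at
#' every channel the summed mu+beta power is identical across classes while
#' the mu-beta power difference is class-lateralized. Construction: each
#' band's hemisphere amplitude pair is swapped between classes — class L
#' gets mu = (m1, m2) / beta = (b1, b2), class R the reverse — with the
#' pairs tied by the sum-invariance constraint `m1^2 - m2^2 = b2^2 - b1^2`
#' and chosen mu-dominant (`m > b` at matched positions) so the
#' power-difference stays positive on both hemispheres, as over a resting
#' sensorimotor cortex, and its asymmetry index is well defined. Derived
#' from the base's largest amplitude `a`: `m = (a, 0.8 a)`,
#' `b = (a/3, sqrt(a^2/9 + 0.36 a^2))`. Because mu and beta share each
#' spatial patch's mixing column, the class covariance matrices are
#' identical in expectation and covariance-based methods (CSP, CCSP) are
#' blind; only the pseudocovariance carries class information.
#'
#' @param base a [synth_config()] with exactly one mu-range and one
#'   beta-range source.
#' @return a new `synth_config`.
#' @export
make_difference_only_config <- function(base) {
  stopifnot(inherits(base, "synth_config"))
  if (length(base$sources) != 2L)
    stop_config("base config must have exactly one mu and one beta source")
  bands <- vapply(base$sources, function(s) s$band_low, 0)
  mu_i <- which.min(bands); beta_i <- which.max(bands)
  if (mu_i == beta_i) stop_config("sources must occupy distinct bands")
  a <- max(unlist(lapply(base$sources, function(s)
    c(s$amp_left_class, s$amp_right_class))))
  m1 <- a; m2 <- 0.8 * a
  b1 <- a / 3
  b2 <- sqrt(b1^2 + m1^2 - m2^2)   # sum invariance per hemisphere
  mu0 <- base$sources[[mu_i]]; beta0 <- base$sources[[beta_i]]
  sources <- list(
    mu = source_spec(mu0$band_low, mu0$band_high,
                     amp_left_class = c(m1, m2), amp_right_class = c(m2, m1),
                     waveform = mu0$waveform, name = mu0$name),
    beta = source_spec(beta0$band_low, beta0$band_high,
                       amp_left_class = c(b1, b2), amp_right_class = c(b2, b1),
                       waveform = beta0$waveform, name = beta0$name)
  )
  synth_config(fs = base$fs, n_samples = base$n_samples,
               n_trials_per_class = base$n_trials_per_class,
               sources = sources, montage = base$montage, mixing = NULL,
               noise_sd = base$noise_sd, amp_jitter_sd = base$amp_jitter_sd,
               seed = base$seed)
}
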