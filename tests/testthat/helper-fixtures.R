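# Shared fixtures, all generated in code at test time.

# random complex trial set with controllable noncircularity
rand_complex_trials <- function(n_tr = 20L, n_ch = 5L, n_s = 100L,
                                imag_scale = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sc <- imag_scale %||% stats::runif(1, 0.2, 2)
  z <- array(complex(real = stats::rnorm(n_tr * n_ch * n_s),
                     imaginary = sc * stats::rnorm(n_tr * n_ch * n_s)),
             c(n_tr, n_ch, n_s))
  M <- matrix(stats::rnorm(n_ch * n_ch), n_ch)
  for (tr in seq_len(n_tr)) z[tr, , ] <- M %*% matrix(z[tr, , ], n_ch)
  structure(list(data = z,
                 labels = rep_len(c("L", "R"), n_tr),
                 channel_names = paste0("ch", seq_len(n_ch)),
                 fs = NA_real_),
            class = "complex_trial_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fnorm <- function(x) sqrt(sum(Mod(x)^2))

# small synthetic dataset reused by several files
small_dataset <- function(n_per_class = 20L, seed = 1L, diff_only = FALSE,
                          ...) {
  cfg <- synth_config(n_trials_per_class = n_per_class, seed = seed, ...)
  if (diff_only) cfg <- make_difference_only_config(cfg)
  generate_dataset(cfg)
}

# deterministic two-channel trials with exact per-trial covariances
# diag(v1) for class L and diag(rev(v1)) for class R
toy_diag_trials <- function(v1 = c(4, 1)) {
  base <- rbind(c(1, -1, 1, -1), c(1, 1, -1, -1))
  mk <- function(v) sqrt(v) * base
  data <- array(0, c(4, 2, 4))
  data[1, , ] <- mk(v1); data[2, , ] <- mk(v1)
  data[3, , ] <- mk(rev(v1)); data[4, , ] <- mk(rev(v1))
  eeg_trial_set(data, c("L", "L", "R", "R"), c("a", "b"), fs = 1)
}
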