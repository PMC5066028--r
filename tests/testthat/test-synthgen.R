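test_that("configuration validation rejects bad inputs", {
  expect_error(source_spec(13, 8, c(1, 1), c(1, 1)), "band_low")
  expect_error(source_spec(8, 13, c(-1, 1), c(1, 1)), "nonnegative")
  expect_error(synth_config(n_samples = 20), "too small")
  expect_error(
    synth_config(mixing = matrix(1, 14, 2)),  # collinear columns
    "rank-deficient")
  expect_error(synth_config(mixing = matrix(rnorm(10), 5, 2)), "mixing must be")
})

test_that("generation is deterministic given the seed", {
  a <- generate_dataset(synth_config(n_trials_per_class = 4, seed = 11))
  b <- generate_dataset(synth_config(n_trials_per_class = 4, seed = 11))
  c <- generate_dataset(synth_config(n_trials_per_class = 4, seed = 12))
  expect_identical(a$trials$data, b$trials$data)
  expect_identical(a$truth$amplitudes, b$truth$amplitudes)
  expect_false(identical(a$trials$data, c$trials$data))
})

test_that("ground truth exposes mixing, amplitudes and band components", {
  ds <- small_dataset(5, seed = 2)
  expect_identical(dim(ds$truth$mixing), c(14L, 2L))
  expect_identical(colnames(ds$truth$amplitudes),
                   c("mu.left", "mu.right", "beta.left", "beta.right"))
  # components + noise == data is not exact (noise drawn after), but the
  # noiseless component sum has the right shape and band content
  expect_identical(dim(ds$truth$components$mu), dim(ds$trials$data))
  mu1 <- ds$truth$components$mu[1, 5, ]  # C3
  pg <- periodogram_bartlett(mu1, 640, 640, fs = 160)
  expect_gt(pg$freqs[which.max(pg$power)], 8)
  expect_lt(pg$freqs[which.max(pg$power)], 13)
})

test_that("pure-tone config puts the periodogram peak in band", {
  src <- source_spec(9, 11, c(1, 1), c(1, 1),
                     waveform = "amplitude_modulated_sinusoid")
  cfg <- synth_config(sources = list(mu = src), noise_sd = 0,
                      n_trials_per_class = 2, amp_jitter_sd = 0, seed = 5)
  ds <- generate_dataset(cfg)
  for (ch in c(5, 6, 11)) {
    pg <- periodogram_bartlett(ds$trials$data[1, ch, ], 640, 640, fs = 160)
    pk <- pg$freqs[which.max(pg$power)]
    expect_gte(pk, 8); expect_lte(pk, 13)
  }
})

test_that("band-power linearity: doubling amplitude quadruples power", {
  mk <- function(amp) {
    src <- source_spec(8, 13, c(amp, amp), c(amp, amp), name = "mu")
    cfg <- synth_config(sources = list(mu = src), noise_sd = 0,
                        n_trials_per_class = 50, amp_jitter_sd = 0.1,
                        seed = 77)
    colMeans(generate_dataset(cfg)$truth$band_powers)
  }
  p1 <- mk(1); p2 <- mk(2)
  expect_equal(unname(p2 / p1), 4, tolerance = 0.15)
})

test_that("symmetric null config has chance-level class statistics", {
  src <- list(mu = source_spec(8, 13, c(1, 1), c(1, 1), name = "mu"),
              beta = source_spec(13, 25, c(1, 1), c(1, 1), name = "beta"))
  ds <- generate_dataset(synth_config(sources = src, n_trials_per_class = 60,
                                      seed = 3))
  pow <- apply(ds$trials$data, 1, function(a) mean(a^2))
  tt <- t.test(pow[ds$trials$labels == "L"], pow[ds$trials$labels == "R"])
  expect_gt(tt$p.value, 0.01)
})

test_that("difference-only construction balances summed band power", {
  cfg <- make_difference_only_config(synth_config(n_trials_per_class = 100,
                                                  seed = 9))
  # analytic: per class, mu^2 + beta^2 amplitude sums match on each hemisphere
  amps <- function(s) rbind(s$amp_left_class, s$amp_right_class)
  tot_L <- amps(cfg$sources$mu)[1, ]^2 + amps(cfg$sources$beta)[1, ]^2
  tot_R <- amps(cfg$sources$mu)[2, ]^2 + amps(cfg$sources$beta)[2, ]^2
  expect_equal(tot_L, tot_R)
  # empirical: per-channel summed band power is class-invariant within 3 SE,
  # while the mu-beta difference separates strongly
  ds <- generate_dataset(cfg)
  comp <- ds$truth$components
  psum <- apply(comp$mu, c(1, 2), function(x) mean(x^2)) +
          apply(comp$beta, c(1, 2), function(x) mean(x^2))
  pdiff <- apply(comp$mu, c(1, 2), function(x) mean(x^2)) -
           apply(comp$beta, c(1, 2), function(x) mean(x^2))
  isL <- ds$trials$labels == "L"
  for (ch in c(5, 6)) {  # C3, C4
    se <- sqrt(var(psum[isL, ch]) / sum(isL) + var(psum[!isL, ch]) / sum(!isL))
    expect_lt(abs(mean(psum[isL, ch]) - mean(psum[!isL, ch])), 3 * se)
    expect_gt(abs(mean(pdiff[isL, ch]) - mean(pdiff[!isL, ch])),
              5 * sd(pdiff[, ch]) / sqrt(nrow(pdiff)))
  }
})

test_that("difference-only swaps each band's amplitudes between classes", {
  cfg <- make_difference_only_config(synth_config(seed = 1))
  expect_equal(cfg$sources$mu$amp_left_class,
               rev(cfg$sources$mu$amp_right_class))
  expect_equal(cfg$sources$beta$amp_left_class,
               rev(cfg$sources$beta$amp_right_class))
  # sum-invariance constraint ties the two bands
  m <- cfg$sources$mu$amp_left_class
  b <- cfg$sources$beta$amp_left_class
  expect_equal(m[1]^2 - m[2]^2, b[2]^2 - b[1]^2)
  # the power difference stays positive on both hemispheres for both classes
  expect_gt(m[1]^2 - b[1]^2, 0)
  expect_gt(m[2]^2 - b[2]^2, 0)
})
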