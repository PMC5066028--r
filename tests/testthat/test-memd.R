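fs <- 160
t_ax <- seq_len(640) / fs

test_that("input contracts are enforced", {
  expect_error(memd_decompose(matrix(1, 1, 640)), "2 channels")
  expect_error(memd_decompose(matrix(1, 2, 32)), "64 samples")
  x <- matrix(rnorm(2 * 640), 2); x[1, 3] <- NA
  expect_error(memd_decompose(x), "non-finite")
  expect_error(memd_decompose(matrix(rnorm(12 * 640), 12),
                              sift_config(n_directions = 10)),
               "n_directions")
})

test_that("constant input returns zero modes and the input as residue", {
  x <- matrix(1.5, 2, 128)
  d <- memd_decompose(x)
  expect_identical(dim(d$imfs)[1], 0L)
  expect_equal(d$residue, x)
})

test_that("a pure tone is captured by the first mode", {
  x <- rbind(sin(2 * pi * 10 * t_ax), cos(2 * pi * 10 * t_ax + 0.3))
  d <- memd_decompose(x)
  expect_gte(sum(d$imfs[1, , ]^2) / sum(x^2), 0.95)
  expect_lt(fnorm(d$residue) / fnorm(x), 0.05)
})

test_that("completeness and mode alignment hold on random input", {
  set.seed(4)
  for (n_ch in c(2L, 4L)) {
    x <- matrix(rnorm(n_ch * 256), n_ch)
    d <- memd_decompose(x, sift_config(n_directions = max(8, 2 * n_ch)))
    rec <- apply(d$imfs, c(2, 3), sum) + d$residue
    expect_lt(fnorm(x - rec) / fnorm(x), 1e-8)
    # alignment: the array shape itself enforces equal mode counts per channel
    expect_identical(dim(d$imfs)[2], n_ch)
  }
})

test_that("quasi-dyadic ordering: zero crossings decrease with mode index", {
  set.seed(8)
  ok <- replicate(5, {
    x <- matrix(rnorm(2 * 512), 2)
    zc <- imf_zero_crossings(memd_decompose(x, sift_config(n_directions = 8)))
    mean(diff(zc) <= 0) >= 0.95
  })
  expect_true(all(ok))
})

test_that("two-tone input separates into band-correct modes", {
  x <- rbind(sin(2 * pi * 4 * t_ax) + sin(2 * pi * 24 * t_ax),
             cos(2 * pi * 4 * t_ax) + 0.9 * sin(2 * pi * 24 * t_ax + 1))
  d <- memd_decompose(x)
  peak <- function(v) {
    pg <- periodogram_bartlett(v, 640, 640, fs = fs)
    pg$freqs[which.max(pg$power)]
  }
  energies <- apply(d$imfs, 1, function(m) sum(m^2))
  top2 <- order(energies, decreasing = TRUE)[1:2]
  peaks <- sort(vapply(top2, function(k) peak(d$imfs[k, 1, ]), 0))
  expect_gt(peaks[1], 2); expect_lt(peaks[1], 6)
  expect_gt(peaks[2], 20); expect_lt(peaks[2], 28)
  # band-pass oracle equivalence
  fast <- top2[which.max(c(peak(d$imfs[top2[1], 1, ]),
                           peak(d$imfs[top2[2], 1, ])))]
  slow <- setdiff(top2, fast)
  expect_gt(cor(as.vector(d$imfs[fast, , ]),
                as.vector(bandpass_fft(x, fs, 20, 28))), 0.9)
  expect_gt(cor(as.vector(d$imfs[slow, , ]),
                as.vector(bandpass_fft(x, fs, 2, 6))), 0.9)
})

test_that("noise-assisted MEMD keeps the original channel count and is deterministic", {
  set.seed(2)
  x <- rbind(sin(2 * pi * 10 * t_ax), cos(2 * pi * 21 * t_ax)) +
    matrix(rnorm(2 * 640, 0, 0.1), 2)
  d1 <- na_memd_decompose(x, seed = 42)
  d2 <- na_memd_decompose(x, seed = 42)
  d3 <- na_memd_decompose(x, seed = 43)
  expect_identical(dim(d1$imfs)[2], 2L)
  expect_identical(d1$imfs, d2$imfs)
  expect_false(identical(d1$imfs, d3$imfs))
  expect_error(na_memd_decompose(x, noise_sd = 0), "noise_sd")
})

test_that("Bartlett periodogram locates tones and satisfies Parseval", {
  x <- sin(2 * pi * 10 * t_ax)
  pg <- periodogram_bartlett(x, 640, 640, fs = fs)
  expect_equal(pg$freqs[which.max(pg$power)], 10)
  w <- 1 - abs((seq_len(640) - 1 - 319.5) / 319.5)
  y <- (x - mean(x)) * w
  expect_equal(sum(pg$power), mean(y^2), tolerance = 0.01)
  expect_true(all(pg$power >= 0))
  # zero input and config errors
  expect_equal(sum(periodogram_bartlett(numeric(640), 640, 640, fs)$power), 0)
  expect_error(periodogram_bartlett(x, nfft = 320, window_len = 640, fs = fs),
               "nfft")
  # white noise is approximately flat: max/median ratio stays moderate
  set.seed(10)
  r <- replicate(20, {
    pg <- periodogram_bartlett(rnorm(2560), 640, 640, fs = fs)
    max(pg$power) / median(pg$power)
  })
  expect_lt(max(r), 30)
})

test_that("rhythm assignment: fixed and auto policies", {
  expect_identical(select_rhythm_imfs(list(structure(
    list(imfs = array(0, c(4, 2, 64))), class = "imf_set"))),
    list(mu_modes = 4L, beta_modes = c(2L, 3L)))
  # auto on synthetic two-band modes
  set.seed(6)
  mk_set <- function() {
    m <- array(0, c(3, 2, 640))
    m[1, , ] <- t(replicate(2, bandpass_fft(rnorm(640), fs, 35, 45)))
    m[2, , ] <- t(replicate(2, bandpass_fft(rnorm(640), fs, 15, 24)))
    m[3, , ] <- t(replicate(2, bandpass_fft(rnorm(640), fs, 9, 12)))
    structure(list(imfs = m, residue = matrix(0, 2, 640), fs = fs),
              class = "imf_set")
  }
  sel <- select_rhythm_imfs(replicate(3, mk_set(), simplify = FALSE),
                            policy = "auto", fs = fs)
  expect_identical(sel$mu_modes, 3L)
  expect_identical(sel$beta_modes, 2L)   # mode 1 (>30 Hz) lands in neither
})

test_that("band reconstruction is additive and spectrally concentrated", {
  set.seed(3)
  x <- rbind(bandpass_fft(rnorm(640), fs, 9, 12) +
               bandpass_fft(rnorm(640), fs, 15, 24),
             bandpass_fft(rnorm(640), fs, 9, 12) +
               bandpass_fft(rnorm(640), fs, 15, 24))
  d <- memd_decompose(x)
  n_modes <- dim(d$imfs)[1]
  expect_equal(reconstruct_band(d, integer(0)), matrix(0, 2, 640))
  expect_equal(reconstruct_band(d, seq_len(n_modes)) + d$residue, x,
               tolerance = 1e-10)
  expect_error(reconstruct_band(d, n_modes + 1L), "out of range")
  # beta-band partial sum concentrates its power in 13-25 Hz
  sel <- select_rhythm_imfs(d, policy = "auto", fs = fs)
  beta <- reconstruct_band(d, sel$beta_modes)
  pg <- periodogram_bartlett(beta[1, ], 640, 640, fs = fs)
  in_band <- pg$freqs >= 13 & pg$freqs <= 25
  expect_gte(sum(pg$power[in_band]) / sum(pg$power), 0.8)
})
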