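test_that("complex/real trial construction centers and combines correctly", {
  set.seed(1)
  d <- c(3, 2, 50)
  mu <- array(rnorm(prod(d), mean = 2), d)
  beta <- array(rnorm(prod(d), mean = -1), d)
  z <- build_complex_trials(mu, beta, c("L", "R", "L"))
  expect_lt(max(abs(apply(Re(z$data), c(1, 2), mean))), 1e-12)
  expect_lt(max(abs(apply(Im(z$data), c(1, 2), mean))), 1e-12)
  r <- build_real_trials(mu, beta, c("L", "R", "L"))
  expect_equal(r$data, {
    ctr <- function(a) sweep(a, c(1, 2), apply(a, c(1, 2), mean))
    ctr(Re(z$data) + Im(z$data))
  })
  # variance additivity of the sum
  v_sum <- var(r$data[1, 1, ])
  expect_equal(v_sum,
               var(mu[1, 1, ]) + var(beta[1, 1, ]) +
                 2 * cov(mu[1, 1, ], beta[1, 1, ]),
               tolerance = 1e-10)
  expect_error(build_complex_trials(mu, beta[, 1, , drop = FALSE],
                                    c("L", "R", "L")), "shape")
  # degenerate limits (4 trials so both classes are fittable)
  d4 <- c(4, 2, 50)
  mu4 <- array(rnorm(prod(d4)), d4)
  lab4 <- c("L", "R", "L", "R")
  z0 <- build_complex_trials(mu4, array(0, d4), lab4)
  cv <- estimate_class_covariances(z0, "none")
  expect_equal(Im(cv$C_L), matrix(0, 2, 2))
  expect_equal(cv$P_L, cv$C_L)
  zeq <- build_complex_trials(mu4, mu4, lab4)
  cveq <- estimate_class_covariances(zeq, "none")
  expect_lt(max(abs(Re(cveq$P_L))), 1e-12)  # E[z_mu^2 - z_beta^2] = 0
})

test_that("covariance estimation matches hand arithmetic and a brute-force oracle", {
  mk_set <- function(vals) {
    z <- array(0i, c(4, 1, 2))
    for (i in 1:4) z[i, 1, ] <- vals
    structure(list(data = z, labels = c("L", "L", "R", "R"),
                   channel_names = "ch1", fs = NA),
              class = "complex_trial_set")
  }
  cv <- estimate_class_covariances(mk_set(c(1, -1)), "none")
  expect_equal(cv$C_L, matrix(1 + 0i, 1, 1))
  expect_equal(cv$P_L, matrix(1 + 0i, 1, 1))
  cv2 <- estimate_class_covariances(mk_set(c(1i, -1i)), "none")
  expect_equal(cv2$C_L, matrix(1 + 0i, 1, 1))
  expect_equal(cv2$P_L, matrix(-1 + 0i, 1, 1))
  # brute-force sum of outer products on a 2-channel 4-sample toy
  tr <- rand_complex_trials(4, 2, 4, seed = 3)
  cv3 <- estimate_class_covariances(tr, "none")
  ora_C <- ora_P <- matrix(0i, 2, 2)
  for (i in which(tr$labels == "L")) {
    A <- matrix(tr$data[i, , ], 2)
    A <- A - rowMeans(A)
    for (s in 1:4) {
      ora_C <- ora_C + A[, s] %*% t(Conj(A[, s])) / 4
      ora_P <- ora_P + A[, s] %*% t(A[, s]) / 4
    }
  }
  expect_equal(cv3$C_L, ora_C / 2, tolerance = 1e-12)
  expect_equal(cv3$P_L, ora_P / 2, tolerance = 1e-12)
  expect_error(estimate_class_covariances(rand_complex_trials(3)), ">= 2 trials")
})

test_that("whitening satisfies its identity and closed forms", {
  w <- whiten(diag(c(4, 1)))
  expect_equal(abs(w$G), diag(c(0.5, 1)), tolerance = 1e-12)
  expect_error(whiten(matrix(0, 2, 2)), "zero")
  set.seed(5)
  for (i in 1:5) {
    A <- matrix(complex(real = rnorm(25), imaginary = rnorm(25)), 5)
    C <- A %*% Conj(t(A)) + diag(5) * 0.1
    w <- whiten(C)
    expect_lt(max(Mod(w$G %*% C %*% Conj(t(w$G)) - diag(w$rank))), 1e-10)
  }
})

test_that("Takagi factorization: closed forms, generative oracle, determinism", {
  tk <- takagi_factorize(diag(c(3, 1)) + 0i)
  expect_equal(tk$lambda, c(3, 1))
  expect_equal(Mod(tk$Y), diag(2), tolerance = 1e-10)
  # 1x1 imaginary: Y = exp(j pi/4) up to sign
  tk1 <- takagi_factorize(matrix(1i, 1, 1))
  expect_equal(tk1$lambda, 1)
  expect_equal(tk1$Y %*% (tk1$lambda * t(tk1$Y)), matrix(1i, 1, 1),
               tolerance = 1e-12)
  # generative oracle: rebuild from a random unitary
  set.seed(6)
  for (i in 1:10) {
    Y0 <- qr.Q(qr(matrix(complex(real = rnorm(16), imaginary = rnorm(16)), 4)))
    L0 <- sort(runif(4, 0.1, 3), decreasing = TRUE)
    P <- Y0 %*% (L0 * t(Y0))
    tk <- takagi_factorize(P)
    expect_equal(tk$lambda, L0, tolerance = 1e-8)
    expect_lt(fnorm(P - tk$Y %*% (tk$lambda * t(tk$Y))) / max(1, fnorm(P)),
              1e-8)
    expect_lt(max(Mod(Conj(t(tk$Y)) %*% tk$Y - diag(4))), 1e-10)
  }
  # repeated singular values (degenerate cluster)
  Y0 <- qr.Q(qr(matrix(complex(real = rnorm(9), imaginary = rnorm(9)), 3)))
  P <- Y0 %*% (c(2, 2, 0.5) * t(Y0))
  tk <- takagi_factorize(P)
  expect_lt(fnorm(P - tk$Y %*% (tk$lambda * t(tk$Y))) / fnorm(P), 1e-8)
  expect_error(takagi_factorize(matrix(c(0, 1, 0, 0), 2)), "not symmetric")
  # determinism
  expect_identical(takagi_factorize(P), takagi_factorize(P))
})

test_that("SUT diagonalizes covariance and pseudocovariance simultaneously", {
  set.seed(7)
  for (i in 1:5) {
    tr <- rand_complex_trials(seed = 100 + i)
    cv <- estimate_class_covariances(tr)
    w <- whiten(cv$C_c)
    tk <- takagi_factorize((function(m) (m + t(m)) / 2)(
      w$G %*% cv$P_c %*% t(w$G)))
    su <- compute_sut(w, tk)
    r <- w$rank
    expect_lt(max(Mod(su$Q %*% cv$C_c %*% Conj(t(su$Q)) - diag(r))), 1e-8)
    expect_lt(max(Mod(su$Q %*% cv$P_c %*% t(su$Q) - diag(tk$lambda))), 1e-8)
    expect_lt(max(Mod(su$Q_hat %*% cv$P_c %*% t(su$Q_hat) - diag(r))), 1e-8)
  }
  # circular data: pseudocovariance vanishes, degenerate path warns
  circ <- rand_complex_trials(40, 3, 4000, imag_scale = 1, seed = 9)
  cv <- estimate_class_covariances(circ)
  expect_lt(fnorm(cv$P_c) / fnorm(cv$C_c), 0.1)
})

test_that("CSP closed form: class-swapped diagonal covariances", {
  bank <- csp_fit(toy_diag_trials(c(4, 1)), normalization = "none")
  expect_equal(bank$eigvals$lambda_L, c(0.8, 0.2), tolerance = 1e-10)
  expect_equal(bank$eigvals$lambda_L + bank$eigvals$lambda_R, c(1, 1),
               tolerance = 1e-10)
  # filters align with coordinate axes (off-diagonals vanish)
  expect_lt(max(abs(bank$W[row(bank$W) != col(bank$W)])), 1e-8)
  expect_gt(min(abs(diag(bank$W))), 0.4)
  expect_error(csp_fit(structure(list(data = array(1i, c(4, 2, 4)),
                                      labels = c("L", "L", "R", "R")),
                                 class = "eeg_trial_set")),
               "real-valued")
})

test_that("fitted banks satisfy the eigen-spectrum identities", {
  tr <- rand_complex_trials(30, 5, 200, seed = 21)
  b <- sutccsp_fit(tr)
  expect_lt(b$diagnostics$cov_sum_dev, 1e-8)
  expect_lt(b$diagnostics$pcov_sum_dev, 1e-8)
  expect_identical(b$variant, "SUTCCSP")
  expect_true(all(diff(b$eigvals$lambda_L) <= 1e-12))
  # CCSP shares W, drops W_hat
  b2 <- ccsp_fit(tr)
  expect_null(b2$W_hat)
  expect_lt(max(Mod(b$W - b2$W)), 1e-7)
  # identical classes: lambda = 1/2
  z <- tr$data
  z[tr$labels == "R", , ] <- z[tr$labels == "L", , ]
  tr_same <- tr; tr_same$data <- z
  b3 <- sutccsp_fit(tr_same)
  expect_equal(b3$eigvals$lambda_L, rep(0.5, length(b3$eigvals$lambda_L)),
               tolerance = 1e-8)
})

test_that("apply_filters is linear and consistent with the eigen-spectra", {
  tr <- rand_complex_trials(30, 4, 200, seed = 22)
  b <- sutccsp_fit(tr)
  f <- apply_filters(b, tr)
  tr2 <- tr; tr2$data <- 2 * tr$data
  f2 <- apply_filters(b, tr2)
  expect_equal(f2$V, 2 * f$V)
  expect_equal(dim(f$V)[2], b$rank)
  # mean per-class variance of V rows tracks lambda_L / lambda_R
  pow <- apply(f$V, c(1, 2), function(v) mean(Mod(v)^2))
  # trace normalization: rescale each trial as the fit did
  pow <- pow / rowSums(apply(tr$data, c(1, 2), function(v) {
    v <- v - mean(v); mean(Mod(v)^2)
  }))
  mL <- colMeans(pow[tr$labels == "L", ])
  expect_equal(mL, b$eigvals$lambda_L, tolerance = 0.05)
  expect_error(apply_filters(b, rand_complex_trials(3, 6, 50, seed = 1)),
               "channels")
})

test_that("permutation equivariance and scale invariance", {
  tr <- rand_complex_trials(20, 4, 100, seed = 30)
  perm <- c(3, 1, 4, 2)
  trp <- tr
  trp$data <- tr$data[, perm, , drop = FALSE]
  b <- sutccsp_fit(tr); bp <- sutccsp_fit(trp)
  expect_equal(Mod(bp$W), Mod(b$W[, perm]), tolerance = 1e-6)
  expect_equal(bp$eigvals$lambda_L, b$eigvals$lambda_L, tolerance = 1e-8)
  # scale invariance under trace normalization
  trs <- tr; trs$data <- 7 * tr$data
  bs <- sutccsp_fit(trs)
  expect_equal(bs$eigvals$lambda_L, b$eigvals$lambda_L, tolerance = 1e-8)
  f1 <- extract_power_features(apply_filters(b, tr)$V,
                               apply_filters(b, tr)$V_hat, tr$labels)
  f2 <- extract_power_features(apply_filters(bs, trs)$V,
                               apply_filters(bs, trs)$V_hat, trs$labels)
  expect_equal(f1$X, f2$X, tolerance = 1e-6)
})

test_that("lateralized fixture: top filter projects contralaterally and patterns recover mixing", {
  ds <- small_dataset(30, seed = 40)
  r <- extract_rhythms(ds, "bandpass")
  z <- build_complex_trials(r$mu, r$beta, r$labels, r$channel_names)
  b <- sutccsp_fit(z)
  pat <- spatial_patterns(b)
  # dominant covariance pattern matches one mixing column (up to sign)
  cors <- abs(cor(abs(pat$display[, 1]), abs(ds$truth$mixing)))
  expect_gt(max(cors), 0.8)
  # difference-only fixture: covariance spectrum flat, pseudocovariance spread
  ds2 <- small_dataset(50, seed = 41, diff_only = TRUE)
  r2 <- extract_rhythms(ds2, "bandpass")
  z2 <- build_complex_trials(r2$mu, r2$beta, r2$labels)
  b2 <- sutccsp_fit(z2)
  expect_lt(max(b2$eigvals$lambda_L) - min(b2$eigvals$lambda_L), 0.2)
  expect_gt(max(b2$eigvals$lambda_hat_L) - min(b2$eigvals$lambda_hat_L), 0.3)
})
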