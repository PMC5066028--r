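#' Complex-valued trial set z = mu + j*beta
#'
#' Builds the complex data that the CCSP/SUTCCSP family operates on: the
#' mu-band series as real part and the beta-band series as imaginary part,
#' each centered per trial and channel. The covariance of z then carries
#' the mu+beta power sum, while the pseudocovariance carries the mu-beta
#' power difference and the mu/beta cross-correlation.
#'
#' @param mu,beta numeric arrays `trial x channel x sample` (same shape).
#' @param labels per-trial class labels, "L"/"R".
#' @param channel_names optional channel names.
#' @param fs sampling rate (metadata).
#' @return a `complex_trial_set` (fields `data`, `labels`,
#'   `channel_names`, `fs`).
#' @export
build_complex_trials <- function(mu, beta, labels, channel_names = NULL,
                                 fs = NA_real_) {
  if (!identical(dim(mu), dim(beta)))
    stop_config("mu and beta arrays must have identical shapes")
  if (length(dim(mu)) != 3L)
    stop_config("expected trial x channel x sample arrays")
  labels <- as.character(labels)
  if (length(labels) != dim(mu)[1L]) stop_config("labels length mismatch")
  ctr <- function(a) sweep(a, c(1L, 2L), apply(a, c(1L, 2L), mean))
  z <- ctr(mu) + 1i * ctr(beta)
  structure(list(data = z, labels = labels,
                 channel_names = channel_names %||%
                   paste0("ch", seq_len(dim(mu)[2L])),
                 fs = fs),
            class = "complex_trial_set")
}

#' @export
print.complex_trial_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Complex trial set: %d trials, %d channels, %d samples\n",
              d[1L], d[2L], d[3L]))
  invisible(x)
}

#' Real summed-rhythm trial set
#'
#' The classical-CSP counterpart of [build_complex_trials()]: the summed
#' real series mu + beta, centered per trial and channel.
#'
#' @inheritParams build_complex_trials
#' @return an [eeg_trial_set()].
#' @export
build_real_trials <- function(mu, beta, labels, channel_names = NULL,
                              fs = NA_real_) {
  if (!identical(dim(mu), dim(beta)))
    stop_config("mu and beta arrays must have identical shapes")
  s <- mu + beta
  s <- sweep(s, c(1L, 2L), apply(s, c(1L, 2L), mean))
  eeg_trial_set(s, labels,
                channel_names %||% paste0("ch", seq_len(dim(mu)[2L])),
                fs)
}

#' Class covariance and pseudocovariance matrices
#'
#' Per-trial sample covariance `A A^H / S` and pseudocovariance
#' `A A^T / S` (A holds zero-mean rows), optionally trace-normalized per
#' trial by the trace of that trial's covariance (one shared scale so the
#' pair stays consistent), then averaged within class. For purely real
#' input P equals C.
#'
#' @param trials a `complex_trial_set` or [eeg_trial_set()].
#' @param normalization `"trace"` (default) or `"none"`.
#' @return a `class_covariances` list: `C_L`, `C_R`, `P_L`, `P_R`,
#'   composites `C_c`, `P_c`, and `n_trials_per_class`.
#' @export
estimate_class_covariances <- function(trials,
                                       normalization = c("trace", "none")) {
  normalization <- match.arg(normalization)
  z <- trials$data
  labels <- trials$labels
  n_cls <- table(factor(labels, levels = c("L", "R")))
  if (any(n_cls < 2L))
    stop_config("each class needs >= 2 trials (have L=%d, R=%d)",
                n_cls[["L"]], n_cls[["R"]])
  n_ch <- dim(z)[2L]
  acc <- list(L = list(C = 0, P = 0), R = list(C = 0, P = 0))
  for (tr in seq_len(dim(z)[1L])) {
    A <- matrix(z[tr, , ], n_ch)
    A <- A - rowMeans(A)
    C_t <- tcrossprod(A, Conj(A)) / ncol(A)
    P_t <- tcrossprod(A, A) / ncol(A)
    if (normalization == "trace") {
      s <- Re(sum(diag(C_t)))
      C_t <- C_t / s
      P_t <- P_t / s
    }
    cls <- labels[tr]
    acc[[cls]]$C <- acc[[cls]]$C + C_t
    acc[[cls]]$P <- acc[[cls]]$P + P_t
  }
  C_L <- hermitize(acc$L$C / n_cls[["L"]])
  C_R <- hermitize(acc$R$C / n_cls[["R"]])
  P_L <- symmetrize(acc$L$P / n_cls[["L"]])
  P_R <- symmetrize(acc$R$P / n_cls[["R"]])
  structure(list(C_L = C_L, C_R = C_R, P_L = P_L, P_R = P_R,
                 C_c = C_L + C_R, P_c = P_L + P_R,
                 n_trials_per_class = as.integer(n_cls),
                 normalization = normalization),
            class = "class_covariances")
}

#' Whitening transform of the composite covariance
#'
#' Eigen-factorizes the Hermitian composite covariance `C_c = U L U^H` and
#' returns `G = L^{-1/2} U^H` so that `G C_c G^H = I` on the retained
#' subspace. Eigenvalues below `rank_tol * max` are dropped; a tiny ridge
#' is added when the condition number exceeds 1e12.
#'
#' @param C_c Hermitian positive semidefinite matrix.
#' @param rank_tol relative eigenvalue cutoff.
#' @return a `whitening_transform`: `U_c`, `lambda_c`, `G`, `rank`.
#' @export
whiten <- function(C_c, rank_tol = 1e-10) {
  C_c <- hermitize(C_c)
  n <- nrow(C_c)
  e <- eigen(C_c, symmetric = TRUE)
  lam <- e$values
  if (max(lam) <= 0) stop_config("composite covariance is zero or negative")
  if (min(lam) <= 0 || max(lam) / max(min(lam), .Machine$double.xmin) > 1e12) {
    eps <- 1e-10 * sum(lam) / n
    C_c <- C_c + diag(eps, n)
    e <- eigen(C_c, symmetric = TRUE)
    lam <- e$values
  }
  keep <- lam > rank_tol * max(lam)
  U <- e$vectors[, keep, drop = FALSE]
  lam <- lam[keep]
  G <- (1 / sqrt(lam)) * Conj(t(U))
  structure(list(U_c = U, lambda_c = lam, G = G, rank = sum(keep),
                 rank_tol = rank_tol),
            class = "whitening_transform")
}

# principal square root of a symmetric unitary block via the commuting
# real-symmetric pair (X, Z), D = X + iZ = O diag(e^{i th}) O^T
sqrtm_sym_unitary <- function(D) {
  if (nrow(D) == 1L) return(matrix(sqrt(as.complex(D[1L, 1L])), 1L, 1L))
  X <- Re(D); Z <- Im(D)
  for (c_mix in c(0.5773503, 0.3183099, 0.7071068)) {
    O <- eigen(X + c_mix * Z, symmetric = TRUE)$vectors
    Dd <- t(O) %*% D %*% O
    if (max(abs(Dd - diag(diag(Dd)))) < 1e-8 * max(abs(Dd)))
      return(O %*% (sqrt(diag(Dd)) * t(O)))
  }
  # fall back: accept the best candidate found
  O %*% (sqrt(diag(Dd)) * t(O))
}

#' Takagi factorization of a complex symmetric matrix
#'
#' Factors `P = Y L Y^T` with `Y` unitary and `L` real, nonnegative and
#' descending. Computed from the SVD `P = U S V^H` with the phase
#' correction `Y = U D^{1/2}`, `D = U^H conj(V)`; clusters of (near-)equal
#' singular values take a blockwise matrix square root of the unitary
#' symmetric coupling block. Column signs are fixed so the
#' largest-magnitude entry of each column has positive real part, making
#' the output deterministic.
#'
#' @param P_sym complex symmetric matrix.
#' @param tol symmetry tolerance (relative).
#' @return a `takagi_factors` list: `Y`, `lambda`, `target`.
#' @export
takagi_factorize <- function(P_sym, tol = 1e-8) {
  nrm <- max(1, fnorm(P_sym))
  if (fnorm(P_sym - t(P_sym)) / nrm > tol)
    stop_config("input is not symmetric within tolerance")
  P <- symmetrize(P_sym)
  s <- svd(P)
  d <- s$d
  n <- length(d)
  D <- Conj(t(s$u)) %*% Conj(s$v)
  # cluster (near-)equal singular values
  S_half <- matrix(0 + 0i, n, n)
  i <- 1L
  ctol <- 1e-8 * max(d, 1)
  while (i <= n) {
    j <- i
    while (j < n && d[j] - d[j + 1L] < ctol) j <- j + 1L
    blk <- i:j
    Db <- symmetrize(D[blk, blk, drop = FALSE])
    S_half[blk, blk] <- sqrtm_sym_unitary(Db)
    i <- j + 1L
  }
  Y <- s$u %*% S_half
  # sign convention (Y and -Y are equivalent per column)
  for (k in seq_len(n)) {
    piv <- which.max(Mod(Y[, k]))
    z <- Y[piv, k]
    flip <- if (abs(Re(z)) > 1e-12 * Mod(z)) Re(z) < 0 else Im(z) < 0
    if (flip) Y[, k] <- -Y[, k]
  }
  structure(list(Y = Y, lambda = d, target = P), class = "takagi_factors")
}

#' Strong uncorrelating transform
#'
#' Combines a whitening transform and the Takagi factors of the whitened
#' composite pseudocovariance into `Q = Y^H G` (so `Q C_c Q^H = I` and
#' `Q P_c Q^T = L`) and `Qhat = L^{-1/2} Y^H G` (so `Qhat P_c Qhat^T = I`).
#' Near-zero Takagi values (near-circular data) are pseudo-inverted to
#' zero with a warning.
#'
#' @param white a [whiten()] result.
#' @param tak a [takagi_factorize()] result for `G P_c G^T`.
#' @return a `sut_transform` list: `Q`, `Q_hat`, `lambda`, `degenerate`.
#' @export
compute_sut <- function(white, tak) {
  if (nrow(tak$Y) != nrow(white$G))
    stop_config("whitening and Takagi dimensions disagree")
  Q <- Conj(t(tak$Y)) %*% white$G
  lam <- tak$lambda
  small <- lam <= 1e-10 * max(lam, 1e-300)
  if (any(small))
    warning(sprintf(
      "%d near-zero pseudocovariance eigenvalue(s): data close to circular; pseudo-inverse square root used",
      sum(small)), call. = FALSE)
  inv_sqrt <- ifelse(small, 0, 1 / sqrt(lam))
  structure(list(Q = Q, Q_hat = inv_sqrt * Q, lambda = lam,
                 degenerate = which(small)),
            class = "sut_transform")
}

# deterministic row scaling: full phase for covariance filters, sign only
# for pseudocovariance filters (congruence by W^T tolerates only +-1)
normalize_rows <- function(W, phase = TRUE) {
  for (r in seq_len(nrow(W))) {
    piv <- which.max(Mod(W[r, ]))
    z <- W[r, piv]
    if (Mod(z) == 0) next
    if (phase) {
      W[r, ] <- W[r, ] * Conj(z) / Mod(z)
    } else {
      flip <- if (abs(Re(z)) > 1e-12 * Mod(z)) Re(z) < 0 else Im(z) < 0
      if (flip) W[r, ] <- -W[r, ]
    }
  }
  W
}

# complex-orthogonal eigensystem of a complex symmetric matrix: columns
# normalized to v^T v = 1, sorted by decreasing real part of eigenvalue
symmetric_eigensystem <- function(S) {
  e <- eigen(S)
  ord <- order(Re(e$values), decreasing = TRUE)
  vals <- e$values[ord]
  V <- e$vectors[, ord, drop = FALSE]
  for (k in seq_len(ncol(V))) {
    q <- sum(V[, k]^2)
    if (Mod(q) < 1e-12) {
      warning("near-defective pseudocovariance eigenvector; congruence accuracy degraded",
              call. = FALSE)
      next
    }
    V[, k] <- V[, k] / sqrt(q)
  }
  list(values = vals, vectors = V)
}

new_filter_bank <- function(W, W_hat, eigvals, variant, channel_names, rank,
                            diagnostics) {
  structure(list(W = W, W_hat = W_hat, eigvals = eigvals, variant = variant,
                 channel_names = channel_names, rank = rank,
                 diagnostics = diagnostics),
            class = "filter_bank")
}

#' @export
print.filter_bank <- function(x, ...) {
  cat(sprintf("%s filter bank: %d filters over %d channels\n",
              x$variant, nrow(x$W), ncol(x$W)))
  cat("  class-L covariance eigenvalues:",
      paste(sprintf("%.3f", x$eigvals$lambda_L), collapse = " "), "\n")
  if (!is.null(x$W_hat))
    cat("  class-L pseudocovariance eigenvalues:",
        paste(sprintf("%.3f", x$eigvals$lambda_hat_L), collapse = " "), "\n")
  invisible(x)
}

#' Fit SUTCCSP spatial filters
#'
#' The full complex pipeline: class covariances/pseudocovariances,
#' whitening of `C_c`, Takagi factorization of the whitened composite
#' pseudocovariance, the strong uncorrelating transform, and joint
#' diagonalization of both class statistics. Returns covariance filters
#' `W` (rows ordered by descending class-L eigenvalue) and
#' pseudocovariance filters `What`, with both eigen-spectra; the defining
#' identities (`lambda_L + lambda_R = I` for both spectra) are verified
#' and reported in `diagnostics`.
#'
#' @param trials a `complex_trial_set` with both classes present.
#' @param normalization passed to [estimate_class_covariances()].
#' @param rank_tol passed to [whiten()].
#' @return a `filter_bank` with `variant = "SUTCCSP"`.
#' @export
sutccsp_fit <- function(trials, normalization = "trace", rank_tol = 1e-10) {
  covs <- estimate_class_covariances(trials, normalization)
  white <- whiten(covs$C_c, rank_tol)
  P_bar <- symmetrize(white$G %*% covs$P_c %*% t(white$G))
  tak <- takagi_factorize(P_bar)
  sut <- compute_sut(white, tak)

  S_L <- hermitize(sut$Q %*% covs$C_L %*% Conj(t(sut$Q)))
  eb <- eigen(S_L, symmetric = TRUE)
  W <- normalize_rows(Conj(t(eb$vectors)) %*% sut$Q, phase = TRUE)
  lambda_L <- eb$values
  S_R <- hermitize(sut$Q %*% covs$C_R %*% Conj(t(sut$Q)))
  lambda_R <- Re(diag(Conj(t(eb$vectors)) %*% S_R %*% eb$vectors))

  Sh_L <- symmetrize(sut$Q_hat %*% covs$P_L %*% t(sut$Q_hat))
  se <- symmetric_eigensystem(Sh_L)
  B_hat <- se$vectors
  B_hat_inv <- tryCatch({
    if (max(Mod(t(B_hat) %*% B_hat - diag(ncol(B_hat)))) < 1e-6) t(B_hat)
    else solve(B_hat)
  }, error = function(e) pinv(B_hat))
  W_hat <- normalize_rows(B_hat_inv %*% sut$Q_hat, phase = FALSE)
  lambda_hat_L <- Re(se$values)
  Sh_R <- symmetrize(sut$Q_hat %*% covs$P_R %*% t(sut$Q_hat))
  lambda_hat_R <- Re(diag(B_hat_inv %*% Sh_R %*% t(B_hat_inv)))

  diagnostics <- list(
    cov_sum_dev = max(abs(lambda_L + lambda_R - 1)),
    pcov_sum_dev = max(abs(lambda_hat_L + lambda_hat_R - 1)),
    takagi_lambda = tak$lambda
  )
  new_filter_bank(W, W_hat,
                  list(lambda_L = lambda_L, lambda_R = lambda_R,
                       lambda_hat_L = lambda_hat_L,
                       lambda_hat_R = lambda_hat_R),
                  "SUTCCSP", trials$channel_names, white$rank, diagnostics)
}

#' Fit complex CSP (covariance only)
#'
#' Same construction as [sutccsp_fit()] but using only the covariance
#' information: complex class covariances are whitened and jointly
#' diagonalized; no pseudocovariance filters are produced. The covariance
#' filters agree with the SUTCCSP `W` (up to the deterministic row
#' scaling), since the strong uncorrelating transform does not change the
#' covariance eigenstructure.
#'
#' @inheritParams sutccsp_fit
#' @return a `filter_bank` with `variant = "CCSP"` and empty `W_hat`.
#' @export
ccsp_fit <- function(trials, normalization = "trace", rank_tol = 1e-10) {
  covs <- estimate_class_covariances(trials, normalization)
  white <- whiten(covs$C_c, rank_tol)
  S_L <- hermitize(white$G %*% covs$C_L %*% Conj(t(white$G)))
  eb <- eigen(S_L, symmetric = TRUE)
  W <- normalize_rows(Conj(t(eb$vectors)) %*% white$G, phase = TRUE)
  S_R <- hermitize(white$G %*% covs$C_R %*% Conj(t(white$G)))
  lambda_R <- Re(diag(Conj(t(eb$vectors)) %*% S_R %*% eb$vectors))
  diagnostics <- list(cov_sum_dev = max(abs(eb$values + lambda_R - 1)))
  new_filter_bank(W, NULL,
                  list(lambda_L = eb$values, lambda_R = lambda_R,
                       lambda_hat_L = NULL, lambda_hat_R = NULL),
                  "CCSP", trials$channel_names, white$rank, diagnostics)
}

#' Fit classical real-valued CSP
#'
#' Joint diagonalization of the whitened real class covariances of the
#' summed-rhythm trials.
#'
#' @param trials an [eeg_trial_set()] (real data) with both classes.
#' @inheritParams sutccsp_fit
#' @return a `filter_bank` with `variant = "CSP"`.
#' @export
csp_fit <- function(trials, normalization = "trace", rank_tol = 1e-10) {
  if (is.complex(trials$data))
    stop_config("csp_fit expects real-valued trials; use ccsp_fit/sutccsp_fit")
  bank <- ccsp_fit(trials, normalization, rank_tol)
  bank$W <- Re(bank$W)
  bank$variant <- "CSP"
  bank
}

#' Apply spatial filters to trials
#'
#' Computes `V = W A` (and `Vhat = What A` when the bank has
#' pseudocovariance filters) for every trial.
#'
#' @param bank a `filter_bank`.
#' @param trials a `complex_trial_set` or [eeg_trial_set()] whose channel
#'   count matches the bank.
#' @return list with `V` (`trial x filter x sample` array), `V_hat`
#'   (same, or `NULL`) and `labels`.
#' @export
apply_filters <- function(bank, trials) {
  z <- trials$data
  if (dim(z)[2L] != ncol(bank$W))
    stop_config("trials have %d channels but bank expects %d",
                dim(z)[2L], ncol(bank$W))
  n_tr <- dim(z)[1L]
  n_f <- nrow(bank$W)
  n_s <- dim(z)[3L]
  cmplx <- is.complex(z) || is.complex(bank$W)
  V <- array(if (cmplx) 0i else 0, c(n_tr, n_f, n_s))
  V_hat <- if (!is.null(bank$W_hat)) array(0i, c(n_tr, nrow(bank$W_hat), n_s))
  for (tr in seq_len(n_tr)) {
    A <- matrix(z[tr, , ], dim(z)[2L])
    V[tr, , ] <- bank$W %*% A
    if (!is.null(V_hat)) V_hat[tr, , ] <- bank$W_hat %*% A
  }
  list(V = V, V_hat = V_hat, labels = trials$labels)
}
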