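#' Power features from filtered trials
#'
#' From the covariance-filtered trials `V` the first and last `m_pairs`
#' components (largest / smallest class-L variance ratio) contribute their
#' per-trial power; with `transform = "log"` the log of the power
#' normalized by the summed power of the selected components is used
#' (scale-invariant). When pseudocovariance-filtered trials `V_hat` are
#' present, each selected component additionally contributes its per-trial
#' circularity-normalized pseudo-power `Re(mean(v^2)) / mean(|v|^2)` — the
#' quantity the pseudocovariance spatial filters separate, already
#' scale-invariant (raw transform uses the unnormalized `Re(mean(v^2))`).
#'
#' @param V `trial x filter x sample` array from [apply_filters()].
#' @param V_hat pseudocovariance-filtered array or `NULL`.
#' @param labels per-trial labels.
#' @param m_pairs number of filter pairs taken from each end.
#' @param transform `"log"` (default) or `"raw"`.
#' @return a `feature_matrix`: `X` (`trial x feature`), `labels`,
#'   `feature_names`, `m_pairs`.
#' @export
extract_power_features <- function(V, V_hat = NULL, labels,
                                   m_pairs = 2L,
                                   transform = c("log", "raw")) {
  transform <- match.arg(transform)
  n_f <- dim(V)[2L]
  if (n_f < 2L * m_pairs)
    stop_config("m_pairs = %d needs >= %d filters, have %d",
                m_pairs, 2L * m_pairs, n_f)
  sel <- c(seq_len(m_pairs), n_f - m_pairs + seq_len(m_pairs))
  ends <- rep(c("top", "bottom"), each = m_pairs)
  n_tr <- dim(V)[1L]

  pow <- matrix(0, n_tr, length(sel))
  for (tr in seq_len(n_tr))
    for (i in seq_along(sel))
      pow[tr, i] <- mean(Mod(V[tr, sel[i], ])^2)
  X <- if (transform == "log") log(pow / rowSums(pow)) else pow
  names_cov <- sprintf("f%d.cov.%s", sel, ends)

  names_pcov <- character(0)
  if (!is.null(V_hat)) {
    n_fh <- dim(V_hat)[2L]
    selh <- c(seq_len(m_pairs), n_fh - m_pairs + seq_len(m_pairs))
    Xh <- matrix(0, n_tr, length(selh))
    for (tr in seq_len(n_tr)) {
      for (i in seq_along(selh)) {
        v <- V_hat[tr, selh[i], ]
        pp <- Re(mean(v^2))
        Xh[tr, i] <- if (transform == "log") pp / mean(Mod(v)^2) else pp
      }
    }
    X <- cbind(X, Xh)
    names_pcov <- sprintf("f%d.pcov.%s", selh, ends)
  }
  if (!all(is.finite(X))) stop_config("non-finite feature values")
  colnames(X) <- c(names_cov, names_pcov)
  structure(list(X = X, labels = as.character(labels),
                 feature_names = colnames(X), m_pairs = as.integer(m_pairs)),
            class = "feature_matrix")
}

#' Append mu/beta power-difference features to CSP features
#'
#' Concatenates per-channel per-trial `var(mu) - var(beta)` features (the
#' power-difference information that the pseudocovariance otherwise
#' carries) to an existing CSP feature matrix — the CSP + PD control
#' condition.
#'
#' @param csp_features a `feature_matrix`.
#' @param mu,beta `trial x channel x sample` arrays.
#' @param channel_names optional names for the PD columns.
#' @return a `feature_matrix` with `ncol(csp) + n_channels` features.
#' @export
combine_csp_pd_features <- function(csp_features, mu, beta,
                                    channel_names = NULL) {
  stopifnot(inherits(csp_features, "feature_matrix"))
  bp <- channel_band_power(mu, beta)
  pd <- bp$P_mu - bp$P_beta
  colnames(pd) <- paste0("pd.", channel_names %||%
                           paste0("ch", seq_len(ncol(pd))))
  X <- cbind(csp_features$X, pd)
  structure(list(X = X, labels = csp_features$labels,
                 feature_names = colnames(X),
                 m_pairs = csp_features$m_pairs),
            class = "feature_matrix")
}
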