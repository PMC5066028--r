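#' Spatial pattern maps of a filter bank
#'
#' The forward-model counterpart of the spatial filters: pattern columns
#' are columns of the (pseudo)inverse of the filter matrix, so
#' `filters %*% patterns = I` on the retained subspace. For complex
#' variants a real display value (magnitude signed by the real part) is
#' provided alongside the raw complex patterns.
#'
#' @param bank a `filter_bank`.
#' @return a `spatial_pattern_map`: `patterns` (channel x component, for
#'   `W`), `patterns_hat` (or `NULL`), `display`/`display_hat` real
#'   matrices, `eigvals`, `channel_names`.
#' @export
spatial_patterns <- function(bank) {
  inv_or_pinv <- function(W) {
    if (nrow(W) == ncol(W)) {
      tryCatch(solve(W), error = function(e) {
        warning("rank-deficient filter matrix; using pseudo-inverse",
                call. = FALSE)
        pinv(W)
      })
    } else pinv(W)
  }
  to_display <- function(A) {
    if (!is.complex(A)) return(A)
    Mod(A) * ifelse(Re(A) >= 0, 1, -1)
  }
  patterns <- inv_or_pinv(bank$W)
  rownames(patterns) <- bank$channel_names
  patterns_hat <- if (!is.null(bank$W_hat)) {
    ph <- inv_or_pinv(bank$W_hat)
    rownames(ph) <- bank$channel_names
    ph
  }
  structure(list(patterns = patterns, patterns_hat = patterns_hat,
                 display = to_display(patterns),
                 display_hat = if (!is.null(patterns_hat)) to_display(patterns_hat),
                 eigvals = bank$eigvals,
                 channel_names = bank$channel_names),
            class = "spatial_pattern_map")
}

#' Per-trial per-channel band powers
#'
#' Power is the variance of the series (mean removed), consistent with the
#' zero-mean trial preprocessing.
#'
#' @param mu,beta `trial x channel x sample` arrays.
#' @return list of `trial x channel` matrices `P_mu`, `P_beta`.
#' @export
channel_band_power <- function(mu, beta) {
  if (!identical(dim(mu), dim(beta))) stop_config("shape mismatch")
  pw <- function(a) {
    a <- sweep(a, c(1L, 2L), apply(a, c(1L, 2L), mean))
    apply(a, c(1L, 2L), function(x) mean(x^2))
  }
  list(P_mu = pw(mu), P_beta = pw(beta))
}

#' Hemispheric asymmetry index
#'
#' `(CH_L - CH_R) / (CH_L + CH_R)`: positive when the left-hemisphere
#' value exceeds the right. Vectorized; a zero denominator yields `NA`
#' (undefined, excluded downstream). Bounded by +-1 for nonnegative
#' inputs and antisymmetric under swapping arguments.
#'
#' @param CH_L,CH_R values at the left / right channel of a symmetric pair.
#' @return asymmetry value(s).
#' @export
asymmetry <- function(CH_L, CH_R) {
  s <- CH_L + CH_R
  ifelse(s == 0, NA_real_, (CH_L - CH_R) / s)
}

#' Exclude outlying asymmetry records
#'
#' Single-pass mean +- `sd_cutoff` * SD exclusion applied within each
#' (pair, quantity) group.
#'
#' @param records data frame with columns `pair`, `quantity`, `asymmetry`
#'   (and any others, preserved).
#' @param sd_cutoff cutoff in standard deviations (default 5).
#' @return list with `records` (kept rows) and `n_excluded`.
#' @export
exclude_outliers <- function(records, sd_cutoff = 5) {
  keep <- rep(TRUE, nrow(records))
  for (g in split(seq_len(nrow(records)),
                  list(records$pair, records$quantity), drop = TRUE)) {
    x <- records$asymmetry[g]
    ok <- is.finite(x)
    m <- mean(x[ok])
    s <- stats::sd(x[ok])
    if (!is.finite(s) || s == 0) {
      keep[g] <- ok
      next
    }
    keep[g] <- ok & abs(x - m) <= sd_cutoff * s
  }
  list(records = records[keep, , drop = FALSE],
       n_excluded = sum(!keep))
}

#' Asymmetry records for symmetric channel pairs
#'
#' For every trial and symmetric (left, right) channel pair, computes the
#' asymmetry index of the mu-beta power difference and of the mu+beta
#' power sum.
#'
#' @param mu,beta `trial x channel x sample` rhythm arrays.
#' @param labels per-trial class labels.
#' @param pairs list of `c(left, right)` channel-name pairs (e.g. from a
#'   [montage_config()]).
#' @param channel_names channel names indexing the arrays' second margin.
#' @return data frame with columns `trial`, `pair`, `class`, `quantity`
#'   (`power_difference` / `power_sum`), `CH_L`, `CH_R`, `asymmetry`.
#' @export
asymmetry_records <- function(mu, beta, labels, pairs, channel_names) {
  bp <- channel_band_power(mu, beta)
  out <- list()
  for (p in pairs) {
    li <- match(p[1L], channel_names)
    ri <- match(p[2L], channel_names)
    if (is.na(li) || is.na(ri))
      stop_config("pair %s-%s not found in channel names", p[1L], p[2L])
    pair_id <- paste(p, collapse = "-")
    for (q in c("power_difference", "power_sum")) {
      chl <- if (q == "power_difference") bp$P_mu[, li] - bp$P_beta[, li]
             else bp$P_mu[, li] + bp$P_beta[, li]
      chr <- if (q == "power_difference") bp$P_mu[, ri] - bp$P_beta[, ri]
             else bp$P_mu[, ri] + bp$P_beta[, ri]
      out[[length(out) + 1L]] <- data.frame(
        trial = seq_along(labels), pair = pair_id, class = labels,
        quantity = q, CH_L = chl, CH_R = chr,
        asymmetry = asymmetry(chl, chr))
    }
  }
  do.call(rbind, out)
}

#' Per-pair per-class asymmetry summary
#'
#' Builds asymmetry records, removes `sd_cutoff`-SD outliers per
#' (pair, quantity) group, and tabulates mean +- SEM per
#' (pair, class, quantity).
#'
#' @inheritParams asymmetry_records
#' @param sd_cutoff outlier cutoff in SD (default 5; `Inf` disables).
#' @return list with `summary` (data frame: `pair`, `class`, `quantity`,
#'   `mean`, `sem`, `n`), `records` (kept records) and `n_excluded`.
#' @export
asymmetry_summary <- function(mu, beta, labels, pairs, channel_names,
                              sd_cutoff = 5) {
  rec <- asymmetry_records(mu, beta, labels, pairs, channel_names)
  filt <- exclude_outliers(rec, sd_cutoff)
  rec <- filt$records
  grp <- split(rec, list(rec$pair, rec$class, rec$quantity), drop = TRUE)
  summary <- do.call(rbind, lapply(grp, function(g) data.frame(
    pair = g$pair[1L], class = g$class[1L], quantity = g$quantity[1L],
    mean = mean(g$asymmetry), sem = sem(g$asymmetry), n = nrow(g))))
  rownames(summary) <- NULL
  list(summary = summary, records = rec, n_excluded = filt$n_excluded)
}
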