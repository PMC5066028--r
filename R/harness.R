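#' Cross-validation configuration
#'
#' Defaults follow the benchmark protocol: stratified 5-fold
#' cross-validation repeated 30 times with freshly shuffled folds.
#'
#' @param k_folds folds per repetition (>= 2).
#' @param repetitions number of repetitions (>= 1).
#' @param seed integer seed; fold assignments and classifier randomness
#'   derive from it, so identical seeds reproduce reports bit-for-bit.
#' @param stratified keep class proportions per fold (always `TRUE`).
#' @return a `cv_config`.
#' @export
cv_config <- function(k_folds = 5L, repetitions = 30L, seed = 1L,
                      stratified = TRUE) {
  stopifnot(k_folds >= 2L, repetitions >= 1L, isTRUE(stratified))
  structure(list(k_folds = as.integer(k_folds),
                 repetitions = as.integer(repetitions),
                 seed = as.integer(seed), stratified = TRUE),
            class = "cv_config")
}

# stratified fold assignment for one repetition (RNG already positioned)
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- sample(which(labels == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Repeated stratified cross-validation
#'
#' Runs `repetitions` independent stratified `k_folds`-fold splits. When
#' `refit_filters` is supplied (a `function(train_idx)` returning a
#' [extract_power_features()] feature matrix for *all* trials, computed
#' with spatial filters fitted on the training indices only), filters and
#' features are re-derived inside every fold so no test information leaks
#' into the fit; otherwise the fixed `features` matrix is used.
#'
#' All fold assignments for all repetitions are drawn up-front from
#' `cfg$seed`, so two calls with the same seed and labels share identical
#' folds regardless of the classifier — the common-random-numbers design
#' that makes paired variant comparisons valid.
#'
#' @param features a `feature_matrix` (supplies labels; may be `NULL` when
#'   `refit_filters` is given together with `labels`).
#' @param clf a `classifier_spec` or a built-in name (`"rf"`, `"knn"`).
#' @param cfg a [cv_config()].
#' @param refit_filters optional fold-wise refitting callback.
#' @param labels labels override when `features` is `NULL`.
#' @param variant tag copied into the report.
#' @return a `classification_report`: `fold_accuracies`
#'   (`repetition x fold`, %), `mean_accuracy` (%), `sem` (% over
#'   repetition means), `classifier_id`, `variant`, `folds` (list of fold
#'   assignments, one integer vector per repetition).
#' @export
repeated_stratified_cv <- function(features, clf, cfg = cv_config(),
                                   refit_filters = NULL, labels = NULL,
                                   variant = NA_character_) {
  clf <- get_classifier(clf)
  labels <- labels %||% features$labels
  n <- length(labels)
  if (min(table(labels)) < cfg$k_folds)
    stop_config("smallest class (%d trials) cannot fill %d folds",
                min(table(labels)), cfg$k_folds)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(cfg$seed)
  folds <- lapply(seq_len(cfg$repetitions), function(r)
    stratified_folds(labels, cfg$k_folds))

  acc <- matrix(NA_real_, cfg$repetitions, cfg$k_folds)
  for (r in seq_len(cfg$repetitions)) {
    fold <- folds[[r]]
    for (f in seq_len(cfg$k_folds)) {
      train <- which(fold != f)
      test <- which(fold == f)
      if (is.null(refit_filters)) {
        Xtr <- features$X[train, , drop = FALSE]
        Xte <- features$X[test, , drop = FALSE]
      } else {
        fm <- refit_filters(train)
        Xtr <- fm$X[train, , drop = FALSE]
        Xte <- fm$X[test, , drop = FALSE]
      }
      model <- clf$fit(Xtr, labels[train])
      pred <- clf$predict(model, Xte)
      acc[r, f] <- 100 * mean(pred == labels[test])
    }
  }
  rep_means <- rowMeans(acc)
  structure(list(fold_accuracies = acc,
                 mean_accuracy = mean(rep_means),
                 sem = if (cfg$repetitions > 1) sem(rep_means) else 0,
                 classifier_id = clf$id, variant = variant, folds = folds,
                 cfg = cfg),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("%s / %s: %.2f +/- %.2f %% (%d x %d-fold CV)\n",
              x$variant, x$classifier_id, x$mean_accuracy, x$sem,
              nrow(x$fold_accuracies), ncol(x$fold_accuracies)))
  invisible(x)
}

#' Fold-wise refitting callback for the CSP family
#'
#' Builds the `refit_filters` callback used by
#' [repeated_stratified_cv()]: given training indices it fits the
#' requested spatial-filter variant on those trials only and returns
#' power features for the full trial set.
#'
#' @param mu,beta `trial x channel x sample` rhythm arrays.
#' @param labels per-trial labels.
#' @param variant `"csp"`, `"ccsp"` or `"sutccsp"`.
#' @param m_pairs filter pairs per end; clamped to half the retained
#'   filter count when the fitted bank has reduced rank.
#' @param transform feature transform, see [extract_power_features()].
#' @param add_pd append per-channel power-difference features (CSP + PD).
#' @return `function(train_idx)` returning a `feature_matrix`.
#' @export
make_csp_refitter <- function(mu, beta, labels,
                              variant = c("sutccsp", "ccsp", "csp"),
                              m_pairs = 2L, transform = "log",
                              add_pd = FALSE) {
  variant <- match.arg(variant)
  function(train_idx) {
    tr_mu <- mu[train_idx, , , drop = FALSE]
    tr_beta <- beta[train_idx, , , drop = FALSE]
    tr_lab <- labels[train_idx]
    if (variant == "csp") {
      bank <- csp_fit(build_real_trials(tr_mu, tr_beta, tr_lab))
      all_set <- build_real_trials(mu, beta, labels)
    } else {
      fit_fun <- if (variant == "sutccsp") sutccsp_fit else ccsp_fit
      bank <- fit_fun(build_complex_trials(tr_mu, tr_beta, tr_lab))
      all_set <- build_complex_trials(mu, beta, labels)
    }
    filt <- apply_filters(bank, all_set)
    m_eff <- min(m_pairs, nrow(bank$W) %/% 2L)
    fm <- extract_power_features(filt$V, filt$V_hat, labels,
                                 m_pairs = m_eff, transform = transform)
    if (add_pd) fm <- combine_csp_pd_features(fm, mu, beta)
    fm
  }
}

#' Significant-subject accuracy threshold
#'
#' The smallest accuracy (in %) that rejects chance-level performance in a
#' one-sided exact binomial test: `100 * k / n` for the smallest `k` with
#' `P(X >= k | n, p = 0.5) <= alpha`. For 45 trials this is about 64%.
#' A normal-approximation variant (`0.5 + z * sqrt(0.25 / n)`) is also
#' available.
#'
#' @param n_trials number of trials (>= 10).
#' @param alpha one-sided significance level.
#' @param method `"exact"` (default) or `"normal"`.
#' @return threshold in percent.
#' @export
significance_threshold <- function(n_trials, alpha = 0.05,
                                   method = c("exact", "normal")) {
  method <- match.arg(method)
  if (n_trials < 10L) stop_config("n_trials must be >= 10")
  if (method == "normal")
    return(100 * (0.5 + stats::qnorm(1 - alpha) * sqrt(0.25 / n_trials)))
  k <- stats::qbinom(alpha, n_trials, 0.5, lower.tail = FALSE)
  # qbinom gives smallest k with P(X > k) <= alpha; want P(X >= k) <= alpha
  while (stats::pbinom(k - 1L, n_trials, 0.5, lower.tail = FALSE) > alpha)
    k <- k + 1L
  100 * k / n_trials
}

#' Pool of significant subjects
#'
#' A subject enters the pool when its mean accuracy exceeds its threshold
#' under *any* of the fitted variants (union rule).
#'
#' @param reports data frame with columns `subject`, `variant`,
#'   `mean_accuracy` (%).
#' @param thresholds threshold in %, either a scalar or a named vector
#'   keyed by subject.
#' @return list with `pool` (subject ids), `flags` (subject x variant
#'   logical matrix).
#' @export
select_significant_subjects <- function(reports, thresholds) {
  stopifnot(all(c("subject", "variant", "mean_accuracy") %in% names(reports)))
  subjects <- unique(reports$subject)
  variants <- unique(reports$variant)
  thr <- if (length(thresholds) == 1L)
    setNames(rep(thresholds, length(subjects)), subjects)
  else thresholds[as.character(subjects)]
  flags <- matrix(FALSE, length(subjects), length(variants),
                  dimnames = list(as.character(subjects), variants))
  for (i in seq_len(nrow(reports))) {
    s <- as.character(reports$subject[i])
    flags[s, reports$variant[i]] <- flags[s, reports$variant[i]] ||
      reports$mean_accuracy[i] > thr[s]
  }
  list(pool = subjects[rowSums(flags) > 0], flags = flags)
}

#' Paired comparison of per-subject accuracies
#'
#' Paired Student's t-test over matched per-subject mean accuracies
#' (two-sided by default). Identical inputs return p = 1.
#'
#' @param reports_a,reports_b numeric vectors of per-subject accuracies,
#'   matched by position.
#' @param alternative `"two.sided"`, `"greater"` or `"less"` (of a - b).
#' @return list with `statistic`, `df`, `p_value`, `mean_diff`.
#' @export
paired_comparison <- function(reports_a, reports_b,
                              alternative = "two.sided") {
  if (length(reports_a) != length(reports_b))
    stop_config("paired inputs must have equal length")
  d <- reports_a - reports_b
  if (stats::sd(d) == 0) {
    # degenerate: zero-variance differences (identical or exact shift)
    if (all(d == 0))
      return(list(statistic = 0, df = length(d) - 1L,
                  p_value = 1, mean_diff = 0))
    return(list(statistic = sign(mean(d)) * Inf, df = length(d) - 1L,
                p_value = 0, mean_diff = mean(d)))
  }
  tt <- stats::t.test(reports_a, reports_b, paired = TRUE,
                      alternative = alternative)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_diff = mean(d))
}
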