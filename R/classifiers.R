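# Built-in classifier backends. Anything else enters through the same
# fit/predict contract: a classifier_spec is a list with
#   id       character tag,
#   fit      function(X, y) -> model,
#   predict  function(model, X) -> character labels.
# No classification library ships with the runtime, so the two built-ins
# (a compact CART-based random forest and 1-nearest-neighbor) are
# implemented here over plain numeric feature matrices.

#' Classifier plug-in specification
#'
#' @param id character identifier used in reports.
#' @param fit `function(X, y)` returning a fitted model object.
#' @param predict `function(model, X)` returning predicted labels.
#' @return a `classifier_spec`.
#' @export
classifier_spec <- function(id, fit, predict) {
  stopifnot(is.function(fit), is.function(predict))
  structure(list(id = id, fit = fit, predict = predict),
            class = "classifier_spec")
}

# ---- CART with gini impurity, numeric features only -------------------

gini_best_split <- function(x, y01) {
  ord <- order(x)
  xs <- x[ord]
  ys <- y01[ord]
  n <- length(ys)
  cum1 <- cumsum(ys)
  tot1 <- cum1[n]
  i <- seq_len(n - 1L)
  valid <- xs[i] < xs[i + 1L]
  if (!any(valid)) return(NULL)
  nl <- i
  nr <- n - i
  l1 <- cum1[i]
  r1 <- tot1 - l1
  # weighted gini after split
  g <- nl * (1 - (l1 / nl)^2 - ((nl - l1) / nl)^2) +
       nr * (1 - (r1 / nr)^2 - ((nr - r1) / nr)^2)
  g[!valid] <- Inf
  k <- which.min(g)
  list(threshold = (xs[k] + xs[k + 1L]) / 2, gini = g[k])
}

grow_tree <- function(X, y01, mtry, min_node = 1L) {
  n <- length(y01)
  n1 <- sum(y01)
  if (n1 == 0L || n1 == n || n <= min_node)
    return(list(leaf = TRUE, vote = as.integer(n1 > n / 2)))
  feats <- sample.int(ncol(X), mtry)
  best <- NULL
  for (f in feats) {
    sp <- gini_best_split(X[, f], y01)
    if (!is.null(sp) && (is.null(best) || sp$gini < best$gini)) {
      best <- sp
      best$feature <- f
    }
  }
  if (is.null(best))
    return(list(leaf = TRUE, vote = as.integer(n1 > n / 2)))
  go_left <- X[, best$feature] <= best$threshold
  list(leaf = FALSE, feature = best$feature, threshold = best$threshold,
       left = grow_tree(X[go_left, , drop = FALSE], y01[go_left], mtry, min_node),
       right = grow_tree(X[!go_left, , drop = FALSE], y01[!go_left], mtry, min_node))
}

predict_tree <- function(tree, X) {
  out <- integer(nrow(X))
  rec <- function(node, idx) {
    if (!length(idx)) return()
    if (node$leaf) {
      out[idx] <<- node$vote
      return()
    }
    go_left <- X[idx, node$feature] <= node$threshold
    rec(node$left, idx[go_left])
    rec(node$right, idx[!go_left])
  }
  rec(tree, seq_len(nrow(X)))
  out
}

#' Random forest backend
#'
#' Bagged CART trees grown to purity (unlimited depth) with `mtry`
#' features sampled per node; prediction by majority vote. Defaults follow
#' the benchmark configuration: 100 trees.
#'
#' @param n_trees number of trees.
#' @param mtry features per split; default `floor(sqrt(p))`.
#' @return a `classifier_spec`.
#' @export
classifier_rf <- function(n_trees = 100L, mtry = NULL) {
  classifier_spec(
    id = sprintf("rf%d", n_trees),
    fit = function(X, y) {
      X <- as.matrix(X)
      lv <- sort(unique(y))
      y01 <- as.integer(y == lv[length(lv)])
      m <- mtry %||% max(1L, floor(sqrt(ncol(X))))
      trees <- vector("list", n_trees)
      for (b in seq_len(n_trees)) {
        idx <- sample.int(nrow(X), replace = TRUE)
        trees[[b]] <- grow_tree(X[idx, , drop = FALSE], y01[idx], m)
      }
      list(trees = trees, levels = lv)
    },
    predict = function(model, X) {
      X <- as.matrix(X)
      votes <- rowSums(vapply(model$trees,
                              function(tree) predict_tree(tree, X),
                              integer(nrow(X))))
      model$levels[1L + as.integer(votes > length(model$trees) / 2)]
    }
  )
}

#' k-nearest-neighbor backend
#'
#' Euclidean 1-NN by default; ties in the vote break toward the nearest
#' neighbor's label (deterministic).
#'
#' @param k neighborhood size.
#' @return a `classifier_spec`.
#' @export
classifier_knn <- function(k = 1L) {
  classifier_spec(
    id = sprintf("knn%d", k),
    fit = function(X, y) list(X = as.matrix(X), y = y),
    predict = function(model, X) {
      X <- as.matrix(X)
      vapply(seq_len(nrow(X)), function(i) {
        d2 <- colSums((t(model$X) - X[i, ])^2)
        nb <- order(d2)[seq_len(min(k, length(d2)))]
        tab <- table(model$y[nb])
        win <- names(tab)[tab == max(tab)]
        if (length(win) == 1L) win else model$y[nb[1L]]
      }, "")
    }
  )
}

#' Resolve a classifier by name
#'
#' @param id `"rf"`, `"knn"`, or a ready `classifier_spec`.
#' @return a `classifier_spec`.
#' @export
get_classifier <- function(id) {
  if (inherits(id, "classifier_spec")) return(id)
  switch(id,
         rf = classifier_rf(),
         knn = classifier_knn(),
         stop_config("unknown classifier '%s' (built-ins: rf, knn)", id))
}
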