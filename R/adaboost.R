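## AdaBoost over shallow weighted-Gini decision trees. Used to aggregate the
## five base-classifier probabilities into the final article probability;
## the trees are grown greedily on midpoint thresholds with ties broken by
## lowest feature index, then smallest threshold.

fit_gini_tree <- function(X, y, w, depth) {
  W <- sum(w)
  wpos <- sum(w[y > 0])
  leaf_value <- if (wpos >= W - wpos) 1 else -1
  if (depth == 0L || wpos == 0 || wpos == W || nrow(X) < 2L) {
    return(list(leaf = leaf_value))
  }
  best <- NULL
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    ord <- order(x)
    xs <- x[ord]; ws <- w[ord]; ys <- y[ord]
    cw <- cumsum(ws)
    cp <- cumsum(ws * (ys > 0))
    valid <- which(xs[-length(xs)] < xs[-1L])
    if (length(valid) == 0L) next
    WL <- cw[valid]; PL <- cp[valid]
    WR <- W - WL; PR <- wpos - PL
    gini <- 2 * PL * (WL - PL) / WL + 2 * PR * (WR - PR) / WR
    b <- which.min(gini)
    score <- gini[b]
    if (is.null(best) || score < best$score - 1e-12) {
      best <- list(score = score, feature = j,
                   threshold = (xs[valid[b]] + xs[valid[b] + 1L]) / 2)
    }
  }
  if (is.null(best)) return(list(leaf = leaf_value))
  go_left <- X[, best$feature] <= best$threshold
  list(feature = best$feature, threshold = best$threshold,
       left = fit_gini_tree(X[go_left, , drop = FALSE], y[go_left],
                            w[go_left], depth - 1L),
       right = fit_gini_tree(X[!go_left, , drop = FALSE], y[!go_left],
                             w[!go_left], depth - 1L))
}

predict_gini_tree <- function(tree, X) {
  if (!is.null(tree$leaf)) return(rep(tree$leaf, nrow(X)))
  out <- numeric(nrow(X))
  go_left <- X[, tree$feature] <= tree$threshold
  if (any(go_left)) out[go_left] <- predict_gini_tree(tree$left, X[go_left, , drop = FALSE])
  if (any(!go_left)) out[!go_left] <- predict_gini_tree(tree$right, X[!go_left, , drop = FALSE])
  out
}

#' Configuration for the boosted-tree probability aggregator
#'
#' Defaults follow the pipeline's aggregation model: 150 boosted trees of
#' maximum depth 2 with learning rate 0.2.
#'
#' @param n_trees Number of boosting rounds.
#' @param max_depth Maximum tree depth.
#' @param learning_rate Shrinkage applied to each round's vote weight.
#' @param blend Share of the mean input feature mixed into the output
#'   probability. The boosted margin is piecewise constant over the feature
#'   space, so inputs landing in the same leaves of every tree would
#'   otherwise tie; blending ranks such ties by mean base probability while
#'   leaving 0.5-threshold decisions unchanged whenever the margin is
#'   confident.
#' @return A list of class `aggregator_config`.
#' @export
aggregator_config <- function(n_trees = 150L, max_depth = 2L, learning_rate = 0.2,
                              blend = 0.05) {
  if (blend < 0 || blend >= 0.5) err_config("blend must be in [0, 0.5)")
  structure(list(n_trees = as.integer(n_trees), max_depth = as.integer(max_depth),
                 learning_rate = learning_rate, blend = blend),
            class = "aggregator_config")
}

fit_adaboost <- function(X, y01, config = aggregator_config()) {
  X <- as.matrix(X)
  y <- ifelse(y01 > 0, 1, -1)
  n <- nrow(X)
  w <- rep(1 / n, n)
  trees <- list(); alphas <- numeric(0)
  for (m in seq_len(config$n_trees)) {
    tree <- fit_gini_tree(X, y, w, config$max_depth)
    pred <- predict_gini_tree(tree, X)
    err <- sum(w[pred != y])
    err <- min(max(err, 1e-10), 1 - 1e-10)
    if (err >= 0.5 && m > 1L) break
    alpha <- config$learning_rate * 0.5 * log((1 - err) / err)
    trees[[length(trees) + 1L]] <- tree
    alphas <- c(alphas, alpha)
    w <- w * exp(-alpha * y * pred)
    w <- w / sum(w)
  }
  structure(list(trees = trees, alphas = alphas, config = config,
                 n_features = ncol(X)), class = "adaboost_model")
}

predict_adaboost <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$n_features) {
    err_contract(sprintf("aggregator expects %d features, got %d",
                         model$n_features, ncol(X)))
  }
  F <- numeric(nrow(X))
  for (m in seq_along(model$trees)) {
    F <- F + model$alphas[m] * predict_gini_tree(model$trees[[m]], X)
  }
  blend <- model$config$blend %||% 0
  (1 - blend) / (1 + exp(-2 * F)) + blend * rowMeans(X)
}

#' @export
print.adaboost_model <- function(x, ...) {
  cat(sprintf("<adaboost_model: %d trees (max depth %d, lr %.3g) over %d features>\n",
              length(x$trees), x$config$max_depth, x$config$learning_rate,
              x$n_features))
  invisible(x)
}
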