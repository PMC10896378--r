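# Importance-reweighted regression forests and signed decision paths.
#
# Forests are grown with `ranger`; the per-split candidate features are
# sampled with probability proportional to a weight vector, which is how the
# iterated scheme concentrates the forest on previously important features.
# A *signed path* is the set of (feature, side) pairs on a root-to-leaf
# path: "+" when the path takes the ">threshold" branch, "-" when it takes
# the "<=threshold" branch.  Leaf sets weighted by their training-sample
# counts are the raw material for the random intersection trees.

#' Forest hyperparameters
#'
#' @param num_trees trees per forest.  The full-scale analysis default is
#'   100 per bootstrap; reduced configurations use fewer.
#' @param max_depth maximum tree depth (bounds the order of discoverable
#'   interactions; depth d paths contain at most d signed features).
#' @param min_node_size minimal leaf size.
#' @param mtry candidate features per split; default `ceiling(sqrt(p))`.
#' @return a list of class `forest_params`.
#' @export
forest_params <- function(num_trees = 100, max_depth = 4, min_node_size = 10,
                          mtry = NULL) {
  structure(list(num_trees = num_trees, max_depth = max_depth,
                 min_node_size = min_node_size, mtry = mtry),
            class = "forest_params")
}

#' Grow a regression forest with weighted feature sampling
#'
#' @param X data frame (or matrix) of features.
#' @param y numeric response.
#' @param feature_weights non-negative per-feature sampling weights, not all
#'   zero; `NULL` for uniform.
#' @param params a [forest_params()].
#' @param seed integer seed for the forest growing.
#' @return a `ranger` forest with attributes `feature_weights` and
#'   `importance` (total impurity decrease per feature).
#' @export
grow_weighted_forest <- function(X, y, feature_weights = NULL,
                                 params = forest_params(), seed = 1L) {
  X <- as.data.frame(X)
  p <- ncol(X)
  if (p == 0) mc_user_error("empty feature set")
  if (nrow(X) < 2) mc_user_error("need at least 2 observations")
  if (is.null(feature_weights)) feature_weights <- rep(1, p)
  if (length(feature_weights) != p || any(feature_weights < 0) ||
      all(feature_weights == 0)) {
    mc_user_error("feature_weights must be non-negative, length ncol(X), not all zero")
  }
  mtry <- min(params$mtry %||% ceiling(sqrt(p)), sum(feature_weights > 0))
  rf <- suppressWarnings(ranger::ranger(
    x = X, y = y,
    num.trees = params$num_trees,
    mtry = mtry,
    min.node.size = params$min_node_size,
    max.depth = params$max_depth,
    split.select.weights = feature_weights / max(feature_weights),
    importance = "impurity",
    num.threads = 1,
    verbose = FALSE,
    seed = seed
  ))
  attr(rf, "feature_weights") <- feature_weights
  rf
}

#' Per-feature importance of a grown forest
#' @param forest a forest from [grow_weighted_forest()].
#' @return named numeric vector (total impurity decrease).
#' @export
forest_importance <- function(forest) {
  ranger::importance(forest)
}

#' Iterate a forest, reweighting features by importance
#'
#' Iteration 1 uses uniform feature weights; iteration k+1 samples split
#' candidates proportionally to iteration k's (non-negative, normalized)
#' impurity importances, so signal features are progressively enriched on
#' the decision paths.
#'
#' @inheritParams grow_weighted_forest
#' @param n_iterations number of iterations (>= 1).
#' @return the final forest, with attribute `iteration_importance` (list of
#'   per-iteration importance vectors).
#' @export
iterate_forest <- function(X, y, n_iterations = 3, params = forest_params(),
                           seed = 1L) {
  if (n_iterations < 1) mc_user_error("n_iterations must be >= 1")
  w <- NULL
  trace <- vector("list", n_iterations)
  for (k in seq_len(n_iterations)) {
    rf <- grow_weighted_forest(X, y, w, params, seed = fan_out_seed(seed, k))
    imp <- pmax(forest_importance(rf), 0)
    trace[[k]] <- imp
    w <- if (sum(imp) == 0) rep(1, length(imp)) else imp / sum(imp)
  }
  attr(rf, "iteration_importance") <- trace
  rf
}

#' Extract weighted signed feature-sets from a forest's leaves
#'
#' For every leaf of every tree, the set of signed features on its
#' root-to-leaf path, weighted by the number of observations of `X` that
#' fall in the leaf.  A feature met with both signs on one path keeps its
#' last-encountered (deepest) sign.  Identical sets are merged with summed
#' weights.  Per tree, the leaf weights sum to `nrow(X)`.
#'
#' @param forest a grown forest.
#' @param X the (training) data whose leaf membership defines the weights.
#' @return list with `sets` (list of character vectors of signed features)
#'   and `weights` (numeric); attribute `n_obs`.
#' @export
extract_signed_paths <- function(forest, X) {
  X <- as.data.frame(X)
  if (forest$num.trees < 1) mc_user_error("empty forest")
  tn <- predict(forest, X, type = "terminalNodes",
                num.threads = 1)$predictions
  vn <- forest$forest$independent.variable.names
  acc <- new.env(parent = emptyenv())
  for (t in seq_len(forest$num.trees)) {
    left <- forest$forest$child.nodeIDs[[t]][[1]]   # 0-based child ids
    right <- forest$forest$child.nodeIDs[[t]][[2]]
    var0 <- forest$forest$split.varIDs[[t]]
    n_nodes <- length(left)
    counts <- tabulate(tn[, t] + 1L, nbins = n_nodes)
    parent <- integer(n_nodes); sign_ch <- character(n_nodes)
    internal <- which(left != 0 | right != 0)
    parent[left[internal] + 1L] <- internal        # parent as 1-based index
    parent[right[internal] + 1L] <- internal
    sign_ch[left[internal] + 1L] <- "-"            # left branch: x <= split
    sign_ch[right[internal] + 1L] <- "+"           # right branch: x > split
    terminals <- which(left == 0 & right == 0 & counts > 0)
    for (leaf in terminals) {
      node <- leaf
      feats <- character(0); signs <- character(0)
      while (node != 1L) {
        par <- parent[node]
        v <- vn[var0[par] + 1L]
        if (!v %in% feats) {        # climbing leaf->root: first hit = deepest
          feats <- c(feats, v); signs <- c(signs, sign_ch[node])
        }
        node <- par
      }
      if (length(feats)) {
        key <- paste(sort(paste0(feats, signs), method = "radix"),
                     collapse = " & ")
        prev <- acc[[key]]
        acc[[key]] <- (if (is.null(prev)) 0 else prev) + counts[leaf]
      }
    }
  }
  keys <- ls(acc)
  structure(list(
    sets = lapply(keys, function(k) strsplit(k, " & ", fixed = TRUE)[[1]]),
    weights = vapply(keys, function(k) acc[[k]], 0, USE.NAMES = FALSE)
  ), n_obs = nrow(X))
}
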