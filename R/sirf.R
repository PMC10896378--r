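# The rh-SiRF engine: repeated-holdout signed iterated random forest.
#
# Per holdout: split the cohort 60/40 into training and test halves, grow an
# iterated (importance-reweighted) forest on the training half, and keep the
# holdout only if the final forest predicts the test half (R^2 above a
# configurable floor) -- discovered combinations must be predictive out of
# sample, not just fitted.  Within a retained holdout, bootstrap the
# training half; each bootstrap regrows a forest under the final feature
# weights, extracts weighted signed leaf sets, and runs random intersection
# trees; a signature counts for the holdout when it appears in a sufficient
# fraction of bootstraps.  Stability of a signature is the fraction of
# holdouts in which it was retained.

#' rh-SiRF configuration
#'
#' Defaults follow the full-scale analysis design: 500 holdouts with a
#' 60/40 train/test partition and 250 bootstraps per holdout; 3 forest
#' iterations.  Reduced configurations (fewer holdouts/bootstraps/trees)
#' are used for simulation studies and testing.
#'
#' @param n_holdouts repeated train/test splits.
#' @param train_fraction training proportion in (0,1).
#' @param n_bootstraps bootstrap resamples per holdout.
#' @param n_iterations forest iterations (importance reweighting rounds).
#' @param forest a [forest_params()] for the per-bootstrap forests.
#' @param iteration_forest a [forest_params()] for the iteration stage.
#'   The iteration forest runs only `n_iterations` times per holdout but its
#'   importances steer everything downstream, so it defaults to more trees
#'   and wider `mtry` than the (many, cheap) bootstrap forests.
#' @param rit a [rit_params()].
#' @param predictivity_floor holdout retained only if the final forest's
#'   test-half R^2 exceeds this floor.
#' @param bootstrap_support a signature counts for a holdout when found in
#'   at least this fraction of its bootstraps.
#' @param max_order signatures above this order are discarded (the
#'   scientific focus is order 2-3).
#' @return a list of class `sirf_config`.
#' @export
sirf_config <- function(n_holdouts = 500, train_fraction = 0.6,
                        n_bootstraps = 250, n_iterations = 3,
                        forest = forest_params(num_trees = 100, max_depth = 3,
                                               min_node_size = 20, mtry = 15),
                        iteration_forest = forest_params(num_trees = 150,
                                                         max_depth = 4,
                                                         min_node_size = 20,
                                                         mtry = 15),
                        rit = rit_params(depth = 2, n_children = 2,
                                         n_trees = 40),
                        predictivity_floor = 0, bootstrap_support = 0.1,
                        max_order = 3) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    mc_user_error("train_fraction must lie in (0, 1)")
  }
  structure(list(n_holdouts = n_holdouts, train_fraction = train_fraction,
                 n_bootstraps = n_bootstraps, n_iterations = n_iterations,
                 forest = forest, iteration_forest = iteration_forest,
                 rit = rit,
                 predictivity_floor = predictivity_floor,
                 bootstrap_support = bootstrap_support,
                 max_order = max_order),
            class = "sirf_config")
}

#' Discover signed clique signatures by rh-SiRF
#'
#' @param table a `cohort_table` with complete exposures and outcome.
#' @param config a [sirf_config()].
#' @param seed integer global seed; results are reproducible given
#'   `(seed, config)` and invariant to the row order of `table` (rows are
#'   canonically ordered by participant id internally).
#' @param outcome outcome column, default `"log_tcdi"`.
#' @return a `stability_records` data frame: `signature`, `order`,
#'   `stability` (fraction of holdouts retaining the signature),
#'   `mean_prevalence` (mean within-holdout bootstrap support among
#'   retaining holdouts), sorted by stability with deterministic
#'   tie-breaking (higher mean support, then lexicographic signature).
#'   Attribute `n_predictive_holdouts` counts holdouts passing the
#'   predictivity filter.
#' @export
rh_sirf <- function(table, config = sirf_config(), seed = 1L,
                    outcome = "log_tcdi") {
  stopifnot(inherits(table, "cohort_table"), inherits(config, "sirf_config"))
  table <- table[order(table$participant_id, method = "radix"), , drop = FALSE]
  expos <- exposures_of(table)
  X <- as.data.frame(table)[, expos, drop = FALSE]
  y <- table[[outcome]]
  if (anyNA(X) || anyNA(y)) mc_user_error("exposures and outcome must be complete")
  n <- nrow(X)
  n_train <- round(config$train_fraction * n)
  if (n_train < 10) mc_user_error("fewer than 10 training rows")

  sig_count <- new.env(parent = emptyenv())   # holdout retention counts
  sig_prev <- new.env(parent = emptyenv())    # summed bootstrap support
  n_predictive <- 0L

  for (h in seq_len(config$n_holdouts)) {
    seed_h <- fan_out_seed(seed, h)
    train <- with_seed(seed_h, sample.int(n, n_train))
    Xtr <- X[train, , drop = FALSE]; ytr <- y[train]
    Xte <- X[-train, , drop = FALSE]; yte <- y[-train]

    final <- iterate_forest(Xtr, ytr, config$n_iterations,
                            config$iteration_forest, seed = seed_h)
    pred <- predict(final, Xte, num.threads = 1)$predictions
    sst <- sum((yte - mean(ytr))^2)
    r2 <- if (sst == 0) 0 else 1 - sum((yte - pred)^2) / sst
    if (r2 <= config$predictivity_floor) next
    n_predictive <- n_predictive + 1L

    imp <- pmax(forest_importance(final), 0)
    w_final <- if (sum(imp) == 0) rep(1, length(imp)) else imp / sum(imp)

    boot_hits <- new.env(parent = emptyenv())
    for (b in seq_len(config$n_bootstraps)) {
      seed_b <- fan_out_seed(seed_h, b)
      idx <- with_seed(seed_b, sample.int(n_train, n_train, replace = TRUE))
      rf_b <- grow_weighted_forest(Xtr[idx, , drop = FALSE], ytr[idx],
                                   w_final, config$forest, seed = seed_b)
      paths <- extract_signed_paths(rf_b, Xtr[idx, , drop = FALSE])
      if (length(paths$sets) == 0) next
      sigs <- random_intersection_trees(paths$sets, paths$weights,
                                        config$rit,
                                        seed = fan_out_seed(seed_h, 100000L + b))
      sigs <- sigs[lengths(strsplit(sigs, " & ", fixed = TRUE)) <=
                     config$max_order]
      for (s in sigs) {
        boot_hits[[s]] <- (boot_hits[[s]] %||% 0L) + 1L
      }
    }
    thresh <- config$bootstrap_support * config$n_bootstraps
    for (s in ls(boot_hits)) {
      if (boot_hits[[s]] >= thresh) {
        sig_count[[s]] <- (sig_count[[s]] %||% 0L) + 1L
        sig_prev[[s]] <- (sig_prev[[s]] %||% 0) +
          boot_hits[[s]] / config$n_bootstraps
      }
    }
  }

  keys <- ls(sig_count)
  out <- data.frame(
    signature = keys,
    order = lengths(strsplit(keys, " & ", fixed = TRUE)),
    stability = vapply(keys, function(s) sig_count[[s]], 0L,
                       USE.NAMES = FALSE) / config$n_holdouts,
    mean_prevalence = vapply(keys, function(s) {
      sig_prev[[s]] / sig_count[[s]]
    }, 0, USE.NAMES = FALSE),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$stability, -out$mean_prevalence, out$signature,
                   method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_predictive_holdouts") <- n_predictive
  attr(out, "config") <- config
  class(out) <- c("stability_records", class(out))
  out
}

#' Network of the top-k clique signatures
#'
#' Nodes are the signed features appearing in the top-k stability records;
#' edges join features co-occurring within a signature.  The closed-loop
#' flag reports whether the union graph contains a cycle visiting at least
#' three distinct nodes (the criterion used to pick a self-reinforcing set
#' of combinations).
#'
#' @param records a `stability_records` data frame (already sorted).
#' @param k how many top signatures to use (>= 2; fewer are used if fewer
#'   records exist).
#' @return list with `nodes`, `edges` (data frame `from`, `to`),
#'   `closed_loop` (logical), and the igraph object `graph`.
#' @export
clique_network <- function(records, k = 3) {
  if (k < 2) mc_user_error("k must be >= 2")
  top <- head(records, k)
  edges <- do.call(rbind, lapply(top$signature, function(s) {
    m <- sort(strsplit(s, " & ", fixed = TRUE)[[1]], method = "radix")
    if (length(m) < 2) return(NULL)
    cmb <- utils::combn(m, 2)
    data.frame(from = cmb[1, ], to = cmb[2, ], stringsAsFactors = FALSE)
  }))
  if (is.null(edges)) edges <- data.frame(from = character(0), to = character(0))
  edges <- unique(edges)
  nodes <- sort(unique(c(edges$from, edges$to)), method = "radix")
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = if (length(nodes)) nodes else NULL)
  # a simple undirected graph has a (>=3-node) cycle iff it is not a forest
  closed <- igraph::vcount(g) > 0 && !igraph::is_forest(g)
  list(nodes = nodes, edges = edges, closed_loop = closed, graph = g)
}
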