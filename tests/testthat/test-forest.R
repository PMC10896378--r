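make_xy <- function(n = 300, p = 6, seed = 1) {
  set.seed(seed)
  X <- as.data.frame(matrix(rnorm(n * p), n, p))
  names(X) <- paste0("V", seq_len(p))
  list(X = X, y = as.numeric(X$V2 > 0.3) + rnorm(n, sd = 0.3))
}

test_that("weighted sampling contracts hold at the extremes", {
  d <- make_xy()
  # all sampling mass on one feature forces every split onto it
  rf <- grow_weighted_forest(d$X, d$y, c(0, 1, 0, 0, 0, 0),
                             forest_params(num_trees = 10, max_depth = 3),
                             seed = 2)
  imp <- forest_importance(rf)
  expect_true(all(imp[names(imp) != "V2"] == 0))
  expect_gt(imp[["V2"]], 0)
  # a constant response admits no informative split
  rf0 <- grow_weighted_forest(d$X, rep(1, 300), NULL,
                              forest_params(num_trees = 10), seed = 3)
  expect_true(all(forest_importance(rf0) == 0))
  expect_error(grow_weighted_forest(d$X, d$y, rep(0, 6)), "not all zero")
  expect_error(grow_weighted_forest(d$X[0, ], numeric(0)), "observations")
})

test_that("a planted step signal dominates the importances", {
  d <- make_xy(n = 500, seed = 5)
  rf <- grow_weighted_forest(d$X, d$y, NULL,
                             forest_params(num_trees = 50, max_depth = 4),
                             seed = 4)
  expect_equal(names(which.max(forest_importance(rf))), "V2")
})

test_that("one iteration equals a uniform-weight forest", {
  d <- make_xy(n = 150, seed = 7)
  it1 <- iterate_forest(d$X, d$y, n_iterations = 1,
                        forest_params(num_trees = 12), seed = 11)
  ref <- grow_weighted_forest(d$X, d$y, rep(1, 6),
                              forest_params(num_trees = 12),
                              seed = fan_out_seed(11, 1))
  expect_equal(predict(it1, d$X, num.threads = 1)$predictions,
               predict(ref, d$X, num.threads = 1)$predictions)
  expect_error(iterate_forest(d$X, d$y, 0), ">= 1")
})

test_that("iteration concentrates weight on the signal feature", {
  shares <- vapply(1:8, function(s) {
    d <- make_xy(n = 300, seed = 20 + s)
    tr <- attr(iterate_forest(d$X, d$y, 3,
                              forest_params(num_trees = 40, max_depth = 4),
                              seed = s), "iteration_importance")
    first <- tr[[1]][["V2"]] / sum(tr[[1]])
    last <- tr[[3]][["V2"]] / sum(tr[[3]])
    last - first
  }, 0)
  expect_gt(median(shares), 0)
})

test_that("signed path extraction mirrors the tree structure", {
  # hand-built depth-1 tree: root splits V1, two leaves with 30/70 samples
  d <- data.frame(V1 = c(rep(0, 30), rep(1, 70)), V2 = rnorm(100))
  y <- c(rep(0, 30), rep(1, 70)) + rnorm(100, sd = 0.01)
  rf <- grow_weighted_forest(d, y, c(1, 0),
                             forest_params(num_trees = 1, max_depth = 1,
                                           min_node_size = 5), seed = 1)
  paths <- extract_signed_paths(rf, d)
  keys <- vapply(paths$sets, paste, "", collapse = " & ")
  expect_setequal(keys, c("V1+", "V1-"))
  expect_equal(sum(paths$weights), 100)           # conservation
  expect_equal(sort(unname(paths$weights)), c(30, 70))
})

test_that("deeper paths carry one sign per feature and conserve weight", {
  set.seed(9)
  d <- data.frame(A = rnorm(200), B = rnorm(200), C = rnorm(200))
  y <- as.numeric(d$A > 0) * as.numeric(d$B < 0.5) + rnorm(200, sd = 0.1)
  rf <- grow_weighted_forest(d, y, NULL,
                             forest_params(num_trees = 5, max_depth = 2,
                                           min_node_size = 10), seed = 2)
  paths <- extract_signed_paths(rf, d)
  expect_equal(sum(paths$weights), 5 * 200)
  for (s in paths$sets) {
    feats <- sub("[+-]$", "", s)
    expect_equal(anyDuplicated(feats), 0)
    expect_true(all(feats %in% c("A", "B", "C")))
  }
})
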