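# a deliberately small configuration: unit tests exercise the mechanics;
# the recovery-power properties live in the acceptance suite
tiny_sirf <- function(n_holdouts = 4, n_bootstraps = 6) {
  sirf_config(
    n_holdouts = n_holdouts, n_bootstraps = n_bootstraps, n_iterations = 2,
    forest = forest_params(num_trees = 8, max_depth = 3, min_node_size = 15,
                           mtry = 10),
    iteration_forest = forest_params(num_trees = 20, max_depth = 3,
                                     min_node_size = 15, mtry = 10),
    rit = rit_params(depth = 2, n_children = 2, n_trees = 15),
    bootstrap_support = 0.1, predictivity_floor = -Inf)
}

test_that("stability records are reproducible and row-order invariant", {
  tab <- small_cohort(n = 120, seed = 31, missing_rate = 0,
                      effect_in_absent = 0.3, effect_in_present = 0.3)
  a <- rh_sirf(tab, tiny_sirf(), seed = 5)
  b <- rh_sirf(tab, tiny_sirf(), seed = 5)
  expect_equal(as.data.frame(a), as.data.frame(b))
  shuffled <- tab[sample(nrow(tab)), , drop = FALSE]
  c <- rh_sirf(shuffled, tiny_sirf(), seed = 5)
  expect_equal(as.data.frame(a), as.data.frame(c))
})

test_that("a single holdout yields all-or-nothing stabilities", {
  tab <- small_cohort(n = 100, seed = 32, missing_rate = 0,
                      effect_in_absent = 0.3, effect_in_present = 0.3)
  rec <- rh_sirf(tab, tiny_sirf(n_holdouts = 1), seed = 2)
  expect_true(all(rec$stability %in% c(0, 1)))
  expect_true(all(rec$order >= 2))
})

test_that("configuration contracts are enforced", {
  tab <- small_cohort(n = 100, seed = 33, missing_rate = 0)
  expect_error(sirf_config(train_fraction = 1.2), "train_fraction")
  expect_error(rh_sirf(tab[1:12, ], tiny_sirf(), seed = 1), "training rows")
  with_na <- tab
  with_na$log_tcdi[1] <- NA
  expect_error(rh_sirf(with_na, tiny_sirf(), seed = 1), "complete")
})

test_that("clique networks detect closed loops", {
  rec <- data.frame(
    signature = c("A+ & B+", "B+ & C-", "A+ & C-"),
    order = 2, stability = c(0.5, 0.4, 0.3), mean_prevalence = 0.2,
    stringsAsFactors = FALSE)
  net <- clique_network(rec, k = 3)
  expect_true(net$closed_loop)
  expect_equal(nrow(net$edges), 3)
  expect_setequal(net$nodes, c("A+", "B+", "C-"))

  rec2 <- data.frame(signature = c("A+ & B+", "C+ & D+"), order = 2,
                     stability = c(0.5, 0.4), mean_prevalence = 0.2,
                     stringsAsFactors = FALSE)
  net2 <- clique_network(rec2, k = 2)
  expect_false(net2$closed_loop)
  expect_equal(nrow(net2$edges), 2)

  rec3 <- data.frame(signature = "A+ & B+", order = 2, stability = 0.5,
                     mean_prevalence = 0.2, stringsAsFactors = FALSE)
  net3 <- clique_network(rec3, k = 2)
  expect_false(net3$closed_loop)
  expect_equal(nrow(net3$edges), 1)
  expect_error(clique_network(rec3, k = 1), ">= 2")
})

test_that("the closed-loop union becomes the working signature", {
  rec <- data.frame(
    signature = c("Co_T3- & Zn_T2+", "Cr_T2- & Zn_T2+", "Co_T3- & Cr_T2-"),
    order = 2, stability = c(0.5, 0.4, 0.3), mean_prevalence = 0.2,
    stringsAsFactors = FALSE)
  sig <- select_signature(rec, k = 3)
  expect_setequal(as.vector(sig), c("Co_T3-", "Cr_T2-", "Zn_T2+"))
  expect_true(attr(sig, "from_closed_loop"))
  # conflicting signs block the union; fall back to the top record
  rec$signature[3] <- "Co_T3+ & Cr_T2-"
  sig2 <- select_signature(rec, k = 3)
  expect_false(attr(sig2, "from_closed_loop"))
})
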