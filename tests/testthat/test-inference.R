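planted_tab <- function(n = 150, seed = 61, ...) {
  pmm_impute(small_cohort(n = n, seed = seed, ...), seed = seed)
}

test_that("clique associations recover a planted common effect", {
  betas <- vapply(1:10, function(s) {
    cfg <- synth_config(n_participants = 500, seed = 600 + s,
                        missing_rate = 0, effect_in_absent = 0.08,
                        effect_in_present = 0.08)
    tab <- generate_cohort(cfg)
    clique_association(tab, cfg$planted_clique)$beta
  }, 0)
  expect_lt(abs(mean(betas) - 0.08), 0.02)
})

test_that("equal weights and degenerate indicators behave as documented", {
  tab <- planted_tab()
  cl <- thresholded_clique(c("Zn_T2", "Co_T3"), c("+", "-"), c(30, 70))
  unw <- clique_association(tab, cl)
  ww <- clique_association(tab, cl, weights = rep(3, nrow(tab)))
  expect_equal(unw$beta, ww$beta, tolerance = 1e-12)
  expect_equal(unw$subgroup_prevalence,
               mean(clique_indicator(cl, tab)))
  all_in <- thresholded_clique("Zn_T2", "-", 100)
  expect_error(clique_association(tab, all_in), "degenerate")
})

test_that("permutation p-values agree with exhaustive enumeration at n = 6", {
  y <- c(0.3, -1.2, 0.7, 2.1, -0.4, 1.0)
  z <- c(0, 0, 1, 1, 0, 1)
  base <- data.frame(participant_id = sprintf("P%d", 1:6), sex = 0,
                     ses = "lower", maternal_age = 30, maternal_bmi = 25,
                     child_age = 9.5, batch = 0, microbe_present = 0,
                     tcdi = 50, pet = 0, stringsAsFactors = FALSE)
  for (k in exposure_keys()) base[[k]] <- 1.0
  tab <- as_cohort_table(base)
  tab$log_tcdi <- y
  tstat <- function(yy) {
    abs(unname(summary(lm(yy ~ z))$coefficients["z", "t value"]))
  }
  t_obs <- tstat(y)
  perms <- all_perms(6)
  t_all <- apply(perms, 1, function(p) tstat(y[p]))
  exact <- mean(t_all >= t_obs - 1e-12)
  p_mc <- permutation_pvalue(tab, z, covariates = character(0),
                             n_permutations = 1e5, seed = 3)
  expect_lt(abs(as.vector(p_mc) - exact), 0.01)
})

test_that("the add-one correction bounds the smallest p-value", {
  tab <- planted_tab(n = 100, seed = 62, effect_in_absent = 2,
                     effect_in_present = 2)
  cfg <- synth_config(n_participants = 100, seed = 62,
                      effect_in_absent = 2, effect_in_present = 2)
  ind <- clique_indicator(cfg$planted_clique, tab)
  p <- permutation_pvalue(tab, as.vector(ind), n_permutations = 199, seed = 1)
  expect_equal(as.vector(p), 1 / 200)
  expect_error(permutation_pvalue(tab, as.vector(ind), n_permutations = 50),
               ">= 99")
})

test_that("stratified and interaction modes agree without covariates", {
  tab <- planted_tab(n = 200, seed = 63)
  cl <- thresholded_clique(c("Zn_T2", "Cr_T2"), c("+", "-"), c(30, 60))
  em <- effect_modification(tab, cl, covariates = character(0),
                            mode = "interaction")
  diff_strata <- em$stratum_present$beta - em$stratum_absent$beta
  expect_equal(em$interaction$beta, diff_strata, tolerance = 1e-10)
  # prevalences partition the overall clique prevalence
  expect_equal(em$prevalence_absent + em$prevalence_present,
               em$overall$subgroup_prevalence, tolerance = 1e-12)
})

test_that("stratified estimates recover opposite-sign planted effects", {
  res <- lapply(1:6, function(s) {
    cfg <- synth_config(n_participants = 1000, seed = 700 + s,
                        missing_rate = 0, effect_in_absent = 0.11,
                        effect_in_present = -0.05)
    tab <- generate_cohort(cfg)
    effect_modification(tab, cfg$planted_clique)
  })
  ab <- vapply(res, function(r) r$stratum_absent$beta, 0)
  pr <- vapply(res, function(r) r$stratum_present$beta, 0)
  expect_lt(abs(mean(ab) - 0.11), 0.03)
  expect_lt(abs(mean(pr) + 0.05), 0.04)
  expect_gt(mean(ab > pr), 0.8)
})

test_that("degenerate strata are flagged inestimable, not dropped", {
  tab <- planted_tab(n = 80, seed = 64)
  # a clique nobody in the microbe-present stratum satisfies
  cl <- thresholded_clique("Zn_T2", "+", 50)
  tab$Zn_T2[tab$microbe_present == 1] <- min(tab$Zn_T2) / 2
  em <- effect_modification(tab, cl)
  expect_true("microbe present" %in% em$inestimable)
  expect_null(em$stratum_present)
  expect_s3_class(em$stratum_absent, "association_result")
})

test_that("binarized-outcome and negative-control analyses stay calibrated", {
  tab <- planted_tab(n = 200, seed = 65)
  cl <- thresholded_clique(c("Zn_T2", "Co_T3"), c("+", "-"), c(30, 70))
  bo <- binarized_outcome_analysis(tab, cl)
  expect_s3_class(bo, "or_result")
  expect_gt(bo$or, 0)
  flat <- tab
  flat$tcdi <- 50
  expect_error(binarized_outcome_analysis(flat, cl), "degenerate")
  nc <- negative_control(tab, cl)
  expect_true(is.logical(nc$consistent_with_null))
  # 2x2 fixture with identical pet rates in and out of clique: OR exactly 1
  n <- 80
  base <- data.frame(participant_id = sprintf("P%d", 1:n), sex = 0,
                     ses = "lower", maternal_age = 30, maternal_bmi = 25,
                     child_age = 9.5, batch = 0, microbe_present = 0,
                     tcdi = 50, stringsAsFactors = FALSE)
  for (k in exposure_keys()) base[[k]] <- 1.0
  base$Zn_T2 <- c(rep(2, 40), rep(1, 40))         # clique = first 40
  base$pet <- rep(c(rep(1, 30), rep(0, 10)), 2)   # [[30,10],[30,10]]
  fx <- as_cohort_table(base)
  half <- thresholded_clique("Zn_T2", "+", 50)
  or1 <- negative_control(fx, half, covariates = character(0))
  expect_equal(or1$or, 1, tolerance = 1e-8)
  expect_true(or1$consistent_with_null)
})
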