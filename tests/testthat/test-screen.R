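test_that("a perfect linear relationship is fitted exactly", {
  tab <- small_cohort(n = 40, seed = 1, missing_rate = 0)
  z <- rnorm(40)
  tab$log_tcdi <- 2 * z
  res <- fit_adjusted(tab, z, covariates = character(0))
  expect_equal(res$beta, 2, tolerance = 1e-10)
  expect_equal(res$ci_high - res$ci_low, 0)
  expect_equal(res$p_model, 0)
})

test_that("a covariate-absorbed confounder leaves the clean coefficient", {
  # y = x + z exactly; adjusting for z must return beta_x = 1 with no error
  n <- 6
  base <- data.frame(participant_id = sprintf("P%d", 1:n),
                     sex = c(0, 1, 0, 1, 0, 1), ses = "lower",
                     maternal_age = 30, maternal_bmi = 25 + 1:n,
                     child_age = 9.5, batch = 0, microbe_present = 0,
                     tcdi = 50, pet = 0, stringsAsFactors = FALSE)
  for (k in exposure_keys()) base[[k]] <- 1.0
  tab <- as_cohort_table(base)
  x <- c(0.3, 1.2, -0.5, 2.2, 0.9, -1.4)
  tab$log_tcdi <- x + tab$maternal_bmi
  res <- fit_adjusted(tab, x, covariates = "maternal_bmi")
  expect_equal(res$beta, 1, tolerance = 1e-10)
})

test_that("uniform weights reproduce the unweighted fit exactly", {
  tab <- small_cohort(n = 90, seed = 3, missing_rate = 0)
  unw <- fit_adjusted(tab, "Zn_T2")
  ww <- fit_adjusted(tab, "Zn_T2", weights = rep(2.5, 90))
  expect_equal(unw$beta, ww$beta, tolerance = 1e-12)
  expect_equal(unw$se, ww$se, tolerance = 1e-12)
})

test_that("degenerate designs raise explicit singularity errors", {
  tab <- small_cohort(n = 30, seed = 4, missing_rate = 0)
  expect_error(fit_adjusted(tab, rep(1, 30), covariates = "sex"), "singular")
  with_na <- tab
  with_na$maternal_age[2] <- NA
  expect_error(fit_adjusted(with_na, "Zn_T2"), "impute")
})

test_that("BH adjustment equals its brute-force definition", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.3), 0.3)
  expect_equal(bh_fdr(c(1, 1)), c(1, 1))
  set.seed(21)
  for (i in 1:25) {
    p <- runif(sample(3:40, 1))
    expect_equal(bh_fdr(p), bh_brute(p), tolerance = 1e-12)
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("screen_all covers every exposure and controls the FDR family", {
  tab <- pmm_impute(small_cohort(n = 112, seed = 6), seed = 1)
  out <- screen_all(tab)
  expect_equal(nrow(out), 23)                      # 22 exposures + microbe
  expect_true(all(exposure_keys() %in% out$term))
  expos <- out[out$term != "microbe_present", ]
  expect_true(all(expos$p_fdr >= expos$p_model - 1e-12))
  expect_equal(bh_fdr(expos$p_model), expos$p_fdr)
  expect_true(is.na(out$p_fdr[out$term == "microbe_present"]))
})

test_that("a strongly planted single-exposure effect ranks first", {
  hits <- vapply(1:10, function(s) {
    tab <- small_cohort(n = 112, seed = 100 + s, missing_rate = 0,
                        planted_clique = NULL)
    tab$log_tcdi <- tab$log_tcdi + 0.1 * scale(log(tab$Pb_T2))[, 1]
    out <- screen_all(tab)
    expos <- out[out$term != "microbe_present", ]
    expos$term[which.min(expos$p_model)] == "Pb_T2"
  }, TRUE)
  expect_gte(mean(hits), 0.7)
})
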