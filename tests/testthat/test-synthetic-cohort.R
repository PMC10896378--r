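test_that("invalid configurations fail loudly", {
  bad_corr <- diag(22); bad_corr[1, 2] <- 0.9; bad_corr[2, 1] <- 0.9
  bad_corr[1, 3] <- 0.9; bad_corr[3, 1] <- 0.9
  bad_corr[2, 3] <- -0.9; bad_corr[3, 2] <- -0.9    # not PSD
  expect_error(synth_config(exposure_corr = bad_corr), "positive semi-definite")
  expect_error(synth_config(microbe_prevalence = 0), "probability")
  expect_error(synth_config(microbe_prevalence = 1.2), "probability")
  expect_error(synth_config(missing_rate = 0.05), "missing_rate")
  asym <- diag(22); asym[1, 2] <- 0.3
  expect_error(synth_config(exposure_corr = asym), "symmetric")
})

test_that("generation is seed-reproducible and respects missing_rate", {
  cfg <- synth_config(n_participants = 80, seed = 5)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  clean <- generate_cohort(synth_config(n_participants = 80, seed = 5,
                                        missing_rate = 0))
  expect_false(anyNA(clean))
  expect_true(all(clean$tcdi >= 0 & clean$tcdi <= 100))
  expos <- as.matrix(as.data.frame(clean)[, exposure_keys()])
  expect_true(all(expos > 0))
})

test_that("null planted effect leaves the outcome unlinked to the clique", {
  cfg <- synth_config(n_participants = 1000, seed = 3,
                      effect_in_absent = 0, effect_in_present = 0,
                      missing_rate = 0)
  tab <- generate_cohort(cfg)
  ind <- clique_indicator(cfg$planted_clique, tab)
  expect_lt(abs(cor(as.vector(ind), tab$log_tcdi, method = "spearman")), 0.2)
})

test_that("microbe prevalence is calibrated (binomial mean over replicates)", {
  counts <- vapply(1:2000, function(s) {
    cfg <- synth_config(n_participants = 112, seed = s)
    sum(generate_cohort(cfg)$microbe_present)
  }, 0)
  # binomial mean 112 * 0.24 = 26.9
  expect_gt(mean(counts), 26.9 - 1)
  expect_lt(mean(counts), 26.9 + 1)
})

test_that("exposure marginals are calibrated on the log scale", {
  cfg <- synth_config(n_participants = 1e5, seed = 9, missing_rate = 0)
  tab <- generate_cohort(cfg)
  for (k in c("Pb_T2", "Zn_T2", "Co_T3", "Cs_T3")) {
    lx <- log(tab[[k]])
    expect_lt(abs(mean(lx) - cfg$exposure_log_mean[[k]]),
              0.02 * abs(cfg$exposure_log_mean[[k]]))
    expect_lt(abs(sd(lx) - cfg$exposure_log_sd[[k]]),
              0.02 * cfg$exposure_log_sd[[k]])
  }
})

test_that("planted truth reports the product-rule prevalence", {
  cfg <- indep_config(planted_clique = thresholded_clique(
    c("Zn_T2", "Co_T3", "Cr_T2"), c("+", "-", "-"), c(20, 80, 55)))
  truth <- planted_truth(cfg)
  expect_equal(truth$expected_prevalence, 0.8 * 0.8 * 0.55)
  # verified by simulation at n = 1e5
  big <- generate_cohort(synth_config(n_participants = 1e5, seed = 2,
                                      exposure_rho = 0, missing_rate = 0))
  sim <- mean(clique_indicator(cfg$planted_clique, big))
  expect_lt(abs(sim - 0.352), 0.01)
  # degenerate percentiles
  one <- indep_config(planted_clique = thresholded_clique("Zn_T2", "+", 0))
  expect_equal(planted_truth(one)$expected_prevalence, 1.0)
  zero <- indep_config(planted_clique = thresholded_clique("Zn_T2", "-", 0))
  expect_equal(planted_truth(zero)$expected_prevalence, 0.0)
  none <- synth_config(planted_clique = NULL)
  expect_error(planted_truth(none), "no planted clique")
})
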