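test_that("propensity fits reduce to closed forms in simple designs", {
  # single binary covariate, group rates 0.2 vs 0.4: the saturated logistic
  # model reproduces the empirical rates
  n <- 1000
  base <- data.frame(participant_id = sprintf("P%d", 1:n),
                     sex = rep(c(0, 1), each = n / 2), ses = "lower",
                     maternal_age = 30, maternal_bmi = 25, child_age = 9.5,
                     batch = 0, tcdi = 50, pet = 0, stringsAsFactors = FALSE)
  for (k in exposure_keys()) base[[k]] <- 1.0
  set.seed(1)
  base$microbe_present <- rbinom(n, 1, ifelse(base$sex == 1, 0.4, 0.2))
  tab <- as_cohort_table(base)
  p <- estimate_propensity(tab, covariates = "sex")
  emp <- as.numeric(tapply(tab$microbe_present, tab$sex, mean))
  expect_equal(sort(unique(round(p, 10))), sort(round(emp, 10)))
  # constant covariate only: all propensities equal the marginal prevalence
  p0 <- estimate_propensity(tab, covariates = "maternal_age")
  expect_equal(unique(round(p0, 10)),
               round(mean(tab$microbe_present), 10))
})

test_that("separation in the propensity model is an explicit error", {
  tab <- small_cohort(n = 60, seed = 51, missing_rate = 0)
  sep <- tab
  sep$maternal_age <- 30 + 10 * sep$microbe_present   # perfect separator
  expect_error(estimate_propensity(sep), "separation")
})

test_that("subclass weights follow the stratified weighting formula", {
  # hand-built 12-row fixture: 2 subclasses x known group counts
  propensity <- c(rep(0.2, 6), rep(0.8, 6))
  group <- c(0, 0, 0, 0, 1, 1,   0, 1, 1, 1, 1, 1)
  sc <- subclassify(propensity, group, n_subclasses = 2)
  N <- 12; N0 <- 5; N1 <- 7
  # subclass 1: n_s = 6, n_{s,0} = 4, n_{s,1} = 2
  expect_equal(unique(sc$weight[1:4]), (6 / N) * (N0 / 4))
  expect_equal(unique(sc$weight[5:6]), (6 / N) * (N1 / 2))
  # subclass 2: n_s = 6, n_{s,0} = 1, n_{s,1} = 5
  expect_equal(unique(sc$weight[7]), (6 / N) * (N0 / 1))
  expect_equal(unique(sc$weight[8:12]), (6 / N) * (N1 / 5))
  # weighted group totals preserve the unweighted group sizes
  expect_equal(sum(sc$weight[group == 0]), N0, tolerance = 1e-12)
  expect_equal(sum(sc$weight[group == 1]), N1, tolerance = 1e-12)
})

test_that("identical group compositions give unit weights", {
  propensity <- rep(c(0.2, 0.4, 0.6, 0.8), each = 4)
  group <- rep(c(0, 1), 8)   # same split in every subclass
  sc <- subclassify(propensity, group, n_subclasses = 4)
  expect_equal(sc$weight, rep(1, 16), tolerance = 1e-12)
})

test_that("subclasses missing a group merge toward the middle", {
  propensity <- c(0.1, 0.12, 0.3, 0.32, 0.6, 0.62, 0.9, 0.92)
  group <- c(0, 0, 0, 1, 0, 1, 1, 1)
  expect_message(sc <- subclassify(propensity, group, n_subclasses = 4),
                 "merging")
  tab <- table(sc$subclass, group)
  expect_true(all(tab > 0))
  expect_gte(sc$n_subclasses_used, 2)
})

test_that("standardized mean differences follow the pooled-SD convention", {
  n <- 40
  base <- data.frame(participant_id = sprintf("P%d", 1:n), sex = 0,
                     ses = "lower", maternal_age = 30, maternal_bmi = 25,
                     child_age = 9.5, batch = 0, microbe_present = rep(c(0, 1), each = n / 2),
                     tcdi = 50, pet = 0, stringsAsFactors = FALSE)
  for (k in exposure_keys()) base[[k]] <- 1.0
  set.seed(2)
  base$maternal_age <- rnorm(n) + base$microbe_present  # means 0 vs 1, sd 1
  tab <- as_cohort_table(base)
  smd <- standardized_mean_differences(tab, covariates = "maternal_age")
  x <- tab$maternal_age; g <- tab$microbe_present
  pooled <- sqrt((var(x[g == 1]) + var(x[g == 0])) / 2)
  expect_equal(unname(smd["maternal_age"]),
               (mean(x[g == 1]) - mean(x[g == 0])) / pooled)
  # identical group means give SMD 0; zero variance is flagged as 0
  flat <- tab
  flat$maternal_age <- 30
  smd0 <- standardized_mean_differences(flat, covariates = "maternal_age")
  expect_equal(unname(smd0["maternal_age"]), 0)
  expect_true("maternal_age" %in% attr(smd0, "zero_variance"))
})

test_that("balancing reduces covariate imbalance on confounded cohorts", {
  improved <- vapply(1:12, function(s) {
    tab <- small_cohort(n = 150, seed = 500 + s, missing_rate = 0,
                        microbe_covariate_link = c(maternal_bmi = -0.12,
                                                   maternal_age = 0.08))
    bal <- suppressMessages(balance_cohort(tab))
    mean(abs(bal$smd_after)) < mean(abs(bal$smd_before))
  }, TRUE)
  expect_gte(mean(improved), 0.75)
})
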