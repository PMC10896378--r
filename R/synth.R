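# Synthetic cohort generator.
#
# Emulates the statistical shape of a prenatal-metals / gut-microbe /
# childhood-depression cohort: 11 metals measured in maternal blood in two
# trimesters (correlated log-normals), a covariate-linked binary microbe
# presence flag, a log-normal t-scored depression outcome, and an optional
# planted thresholded clique whose effect on the log outcome differs between
# microbe-present and microbe-absent children.  Every downstream stage of the
# package is testable against cohorts drawn from this generator.

MC_METALS <- c("Pb", "As", "Cd", "Cr", "Zn", "Se", "Sb", "Cu", "Cs", "Co", "Mn")
MC_TRIMESTERS <- c("T2", "T3")

#' Exposure column names for a metal/trimester grid
#' @param metals,trimesters character vectors.
#' @return character vector `<metal>_<trimester>`, trimester-major.
#' @export
exposure_keys <- function(metals = MC_METALS, trimesters = MC_TRIMESTERS) {
  as.vector(outer(metals, trimesters, function(m, t) paste0(m, "_", t)))
}

# Typical maternal-blood geometric means (ug/L); essential, homeostatically
# regulated elements (Zn, Se, Cu) get a tighter log-sd than trace toxicants.
default_log_means <- function(keys) {
  gm <- c(Pb = 35, As = 1.2, Cd = 0.45, Cr = 0.9, Zn = 4800, Se = 145,
          Sb = 0.25, Cu = 1300, Cs = 2.1, Co = 0.35, Mn = 16)
  setNames(log(gm[sub("_.*$", "", keys)]), keys)
}

default_log_sds <- function(keys) {
  tight <- c("Zn", "Se", "Cu")
  setNames(ifelse(sub("_.*$", "", keys) %in% tight, 0.2, 0.45), keys)
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults reproduce the study conditions the package is designed around:
#' n = 112 participants, 11 metals x 2 trimesters of weakly correlated
#' (exchangeable rho = 0.2 on the latent Gaussian scale) log-normal blood
#' concentrations, microbe prevalence 24%, a t-scored outcome with mean 53
#' and SD 8.1, child sex 60.7% male, a 3-level SES split of roughly
#' 0.55/0.37/0.09, and under-5% missingness confined to maternal age and
#' child age.  The default planted clique is high Zn (2nd trimester, above
#' the 20th percentile), low Co (3rd trimester, below the 80th percentile),
#' low Cr (2nd trimester, below the 55th percentile) with log-scale effects
#' +0.11 in microbe-absent children and -0.05 in microbe-present children.
#'
#' @param n_participants cohort size.
#' @param metal_names,trimesters identifiers forming the exposure grid.
#' @param exposure_log_mean,exposure_log_sd named per-exposure log-scale
#'   parameters (ug/L scale after exponentiation).
#' @param exposure_corr symmetric positive-semidefinite correlation matrix on
#'   the latent Gaussian scale; default exchangeable with `exposure_rho`.
#' @param exposure_rho exchangeable correlation used when `exposure_corr` is
#'   not supplied.
#' @param microbe_prevalence target microbe presence proportion in (0,1).
#' @param microbe_covariate_link named coefficients linking (centered)
#'   covariates to microbe log-odds; the intercept is calibrated so the
#'   expected prevalence equals `microbe_prevalence`.
#' @param outcome_mean,outcome_sd t-score scale mean and SD of the outcome.
#' @param planted_clique optional [thresholded_clique()] to plant, or `NULL`.
#' @param effect_in_absent,effect_in_present log-outcome-scale effects of the
#'   planted clique indicator in microbe-absent / microbe-present children.
#' @param covariate_effects named log-outcome-scale coefficients of centered
#'   covariates.
#' @param missing_rate MCAR missingness proportion applied to maternal age
#'   and child age; must stay below 0.05.
#' @param seed integer seed; identical seeds give bitwise-identical cohorts.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_participants = 112,
                         metal_names = MC_METALS,
                         trimesters = MC_TRIMESTERS,
                         exposure_log_mean = NULL,
                         exposure_log_sd = NULL,
                         exposure_corr = NULL,
                         exposure_rho = 0.2,
                         microbe_prevalence = 0.24,
                         microbe_covariate_link = c(maternal_bmi = -0.06,
                                                    maternal_age = -0.04),
                         outcome_mean = 53.0,
                         outcome_sd = 8.1,
                         planted_clique = thresholded_clique(
                           c("Zn_T2", "Co_T3", "Cr_T2"),
                           c("+", "-", "-"), c(20, 80, 55)),
                         effect_in_absent = 0.11,
                         effect_in_present = -0.05,
                         covariate_effects = c(sex = 0.02),
                         missing_rate = 0.03,
                         seed = 1L) {
  keys <- exposure_keys(metal_names, trimesters)
  if (is.null(exposure_log_mean)) exposure_log_mean <- default_log_means(keys)
  if (is.null(exposure_log_sd)) exposure_log_sd <- default_log_sds(keys)
  if (is.null(exposure_corr)) {
    k <- length(keys)
    exposure_corr <- matrix(exposure_rho, k, k)
    diag(exposure_corr) <- 1
  }
  cfg <- structure(list(
    n_participants = as.integer(n_participants),
    metal_names = metal_names, trimesters = trimesters,
    exposure_keys = keys,
    exposure_log_mean = exposure_log_mean[keys],
    exposure_log_sd = exposure_log_sd[keys],
    exposure_corr = exposure_corr,
    microbe_prevalence = microbe_prevalence,
    microbe_covariate_link = microbe_covariate_link,
    outcome_mean = outcome_mean, outcome_sd = outcome_sd,
    planted_clique = planted_clique,
    effect_in_absent = effect_in_absent,
    effect_in_present = effect_in_present,
    covariate_effects = covariate_effects,
    missing_rate = missing_rate,
    seed = as.integer(seed)
  ), class = "synth_config")
  validate_synth_config(cfg)
}

#' @noRd
validate_synth_config <- function(cfg) {
  assert_scalar_prob(cfg$microbe_prevalence, "microbe_prevalence")
  if (cfg$n_participants < 2) mc_user_error("n_participants must be >= 2")
  if (!is.numeric(cfg$missing_rate) || cfg$missing_rate < 0 ||
      cfg$missing_rate >= 0.05) {
    mc_user_error("missing_rate must lie in [0, 0.05)")
  }
  C <- cfg$exposure_corr
  k <- length(cfg$exposure_keys)
  if (!is.matrix(C) || nrow(C) != k || ncol(C) != k) {
    mc_user_error("exposure_corr must be a %d x %d matrix", k, k)
  }
  if (max(abs(C - t(C))) > 1e-10 || max(abs(diag(C) - 1)) > 1e-10) {
    mc_user_error("exposure_corr must be symmetric with unit diagonal")
  }
  if (min(eigen(C, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    mc_user_error("exposure_corr is not positive semi-definite")
  }
  if (anyNA(cfg$exposure_log_mean) || anyNA(cfg$exposure_log_sd)) {
    mc_user_error("exposure_log_mean / exposure_log_sd must cover all exposures")
  }
  cfg
}

#' @noRd
lognormal_pars <- function(mean, sd) {
  s2 <- log(1 + (sd / mean)^2)
  list(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

# Covariate matrix used for the microbe link and outcome effects, centered.
centered_covariates <- function(tab) {
  cbind(sex = tab$sex - mean(tab$sex),
        ses_medium = (tab$ses == "medium") - mean(tab$ses == "medium"),
        ses_higher = (tab$ses == "higher") - mean(tab$ses == "higher"),
        maternal_age = tab$maternal_age - mean(tab$maternal_age),
        maternal_bmi = tab$maternal_bmi - mean(tab$maternal_bmi),
        child_age = tab$child_age - mean(tab$child_age),
        batch = tab$batch - mean(tab$batch))
}

#' Generate a synthetic cohort table
#'
#' Draws covariates, correlated log-normal exposures (Gaussian copula on the
#' log scale), a covariate-linked microbe flag, the log-normal outcome with
#' the planted clique-by-microbe interaction, an independent binary
#' negative-control outcome (pet ownership), and MCAR missingness on
#' maternal age and child age.
#'
#' @param config a [synth_config()].
#' @return a `cohort_table` data frame (one row per participant) with
#'   attribute `synth_seed`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  validate_synth_config(config)
  n <- config$n_participants
  keys <- config$exposure_keys
  with_seed(config$seed, {
    tab <- data.frame(
      participant_id = sprintf("P%04d", seq_len(n)),
      stringsAsFactors = FALSE
    )
    tab$sex <- rbinom(n, 1, 0.607)                      # 1 = male
    tab$ses <- factor(sample(c("lower", "medium", "higher"), n, replace = TRUE,
                             prob = c(0.545, 0.366, 0.089)),
                      levels = c("lower", "medium", "higher"))
    tab$maternal_age <- pmin(pmax(rnorm(n, 28.7, 5.8), 18), 45)
    tab$maternal_bmi <- pmin(pmax(rnorm(n, 27.3, 4.5), 16), 45)
    tab$child_age <- pmin(pmax(rnorm(n, 9.7, 0.9), 8), 12)
    tab$batch <- rbinom(n, 1, 0.59)

    # exposures: eigen factor handles PSD-but-singular correlation matrices
    eg <- eigen(config$exposure_corr, symmetric = TRUE)
    L <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), length(eg$values))
    Z <- matrix(rnorm(n * length(keys)), n) %*% t(L)
    E <- exp(sweep(sweep(Z, 2, config$exposure_log_sd, `*`),
                   2, config$exposure_log_mean, `+`))
    colnames(E) <- keys
    tab <- cbind(tab, as.data.frame(E))

    # microbe flag: logistic in centered covariates, intercept calibrated so
    # the expected prevalence matches the target exactly
    cc <- centered_covariates(tab)
    link <- config$microbe_covariate_link
    lp <- if (length(link)) {
      as.vector(cc[, names(link), drop = FALSE] %*% link)
    } else rep(0, n)
    icpt <- stats::uniroot(
      function(a) mean(plogis(a + lp)) - config$microbe_prevalence,
      c(-30, 30))$root
    tab$microbe_present <- rbinom(n, 1, plogis(icpt + lp))

    # outcome: log-normal calibrated to the t-score mean/SD, plus centered
    # covariate effects and the planted clique-by-microbe interaction
    pars <- lognormal_pars(config$outcome_mean, config$outcome_sd)
    eta <- rep(pars$meanlog, n)
    ce <- config$covariate_effects
    if (length(ce)) eta <- eta + as.vector(cc[, names(ce), drop = FALSE] %*% ce)
    if (!is.null(config$planted_clique)) {
      ind <- as.vector(clique_indicator(config$planted_clique, tab))
      eff <- config$effect_in_absent * ind * (1 - tab$microbe_present) +
        config$effect_in_present * ind * tab$microbe_present
      eta <- eta + eff - mean(eff)   # centered: marginal mean stays calibrated
    }
    tab$tcdi <- pmin(exp(eta + rnorm(n, 0, pars$sdlog)), 100)
    tab$log_tcdi <- log(tab$tcdi)

    # negative-control outcome: independent of everything by construction
    tab$pet <- rbinom(n, 1, 0.5)

    if (config$missing_rate > 0) {
      for (col in c("maternal_age", "child_age")) {
        tab[[col]][runif(n) < config$missing_rate] <- NA_real_
      }
    }
    structure(as_cohort_table(tab), synth_seed = config$seed)
  })
}

#' Ground truth of the planted clique
#'
#' Returns the planted thresholded clique, its stratum effects, and the
#' subgroup prevalence implied by the percentile thresholds: the exact
#' product rule \eqn{\prod (1 - p_j/100)} for "+" members and
#' \eqn{\prod p_j/100} for "-" members when exposures are independent, and a
#' deterministic 1e5-draw Monte-Carlo estimate under the configured copula
#' otherwise.
#'
#' @param config a [synth_config()] with a planted clique.
#' @return list with `clique`, `signature`, `effect_in_absent`,
#'   `effect_in_present`, `expected_prevalence`.
#' @export
planted_truth <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  if (is.null(config$planted_clique)) {
    mc_user_error("config has no planted clique")
  }
  m <- config$planted_clique$members
  off_diag <- config$exposure_corr
  diag(off_diag) <- 0
  if (max(abs(off_diag)) < 1e-12) {
    prev <- prod(ifelse(m$sign == "+", 1 - m$percentile / 100,
                        m$percentile / 100))
  } else {
    prev <- with_seed(fan_out_seed(config$seed, 990L), {
      big <- config
      big$n_participants <- 100000L
      eg <- eigen(config$exposure_corr, symmetric = TRUE)
      L <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), length(eg$values))
      Z <- matrix(rnorm(1e5 * length(config$exposure_keys)), 1e5) %*% t(L)
      E <- exp(sweep(sweep(Z, 2, config$exposure_log_sd, `*`),
                     2, config$exposure_log_mean, `+`))
      colnames(E) <- config$exposure_keys
      mean(clique_indicator(config$planted_clique, as.data.frame(E)))
    })
  }
  list(clique = config$planted_clique,
       signature = clique_signature(config$planted_clique),
       effect_in_absent = config$effect_in_absent,
       effect_in_present = config$effect_in_present,
       expected_prevalence = prev)
}
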