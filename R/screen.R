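# Covariate-adjusted single-exposure screening with FDR control.

#' Fit one covariate-adjusted association
#'
#' Ordinary (or weighted) least squares of the outcome on a focal term plus
#' the covariate set, with a t-based 95% CI on the focal coefficient.
#' Categorical covariates enter as indicator contrasts.  Rank deficiency
#' involving the focal term or a covariate raises an explicit error rather
#' than silently aliasing.
#'
#' @param table a `cohort_table` with no missing cells among the model
#'   variables (run [pmm_impute()] first).
#' @param term name of the focal column, or a numeric vector of length
#'   `nrow(table)` (supply `term_name` for labelling).
#' @param outcome outcome column, default `"log_tcdi"`.
#' @param covariates covariate column names; `character(0)` for an
#'   unadjusted fit.
#' @param weights optional positive balancing weights.
#' @param term_name label used when `term` is a vector.
#' @param conf_level confidence level for the interval.
#' @return an `association_result`: a list with `term`, `beta`, `se`,
#'   `ci_low`, `ci_high`, `p_model`, `n`, `df_resid` (and slots `p_fdr`,
#'   `p_rand`, `subgroup_prevalence` filled by callers).
#' @export
fit_adjusted <- function(table, term, outcome = "log_tcdi",
                         covariates = covariate_names(), weights = NULL,
                         term_name = NULL, conf_level = 0.95) {
  df <- as.data.frame(table)
  if (is.character(term) && length(term) == 1) {
    term_name <- term_name %||% term
    if (!term %in% names(df)) mc_user_error("term column '%s' not found", term)
    z <- df[[term]]
  } else {
    term_name <- term_name %||% "term"
    z <- as.numeric(term)
    if (length(z) != nrow(df)) mc_user_error("term vector length mismatch")
  }
  dat <- droplevels(data.frame(.y = df[[outcome]], .z = z,
                               df[, covariates, drop = FALSE]))
  if (anyNA(dat)) mc_user_error("missing cells in model variables; impute first")
  # a factor covariate collapsing to one level (e.g. within a stratum)
  # carries no adjustment information and would break the contrasts
  single <- covariates[vapply(covariates, function(cl) {
    is.factor(dat[[cl]]) && nlevels(dat[[cl]]) < 2
  }, TRUE)]
  if (length(single)) {
    message("fit_adjusted: dropping single-level covariate(s): ",
            paste(single, collapse = ", "))
    covariates <- setdiff(covariates, single)
  }
  if (!is.null(weights)) {
    if (length(weights) != nrow(dat) || any(!is.finite(weights)) ||
        any(weights <= 0)) {
      mc_user_error("weights must be positive and finite, one per row")
    }
    dat$.w <- weights
  }
  fml <- as.formula(paste(".y ~ .z",
                          if (length(covariates))
                            paste("+", paste(covariates, collapse = " + "))
                          else ""))
  fit <- if (is.null(weights)) lm(fml, data = dat)
         else lm(fml, data = dat, weights = .w)
  cf <- coef(fit)
  if (anyNA(cf)) {
    mc_user_error("singular model fit (aliased: %s) for term '%s'",
                  paste(names(cf)[is.na(cf)], collapse = ", "), term_name)
  }
  if (fit$df.residual <= 0) mc_user_error("no residual degrees of freedom")
  beta <- cf[[".z"]]
  # a zero-residual fit triggers a benign "essentially perfect fit" warning
  se <- sqrt(suppressWarnings(diag(vcov(fit)))[[".z"]])
  dfres <- fit$df.residual
  if (se == 0) {
    tval <- Inf; p <- 0; half <- 0
  } else {
    tval <- beta / se
    p <- 2 * pt(-abs(tval), dfres)
    half <- qt(1 - (1 - conf_level) / 2, dfres) * se
  }
  structure(list(term = term_name, beta = beta, se = se,
                 ci_low = beta - half, ci_high = beta + half,
                 t = tval, p_model = p, p_fdr = NA_real_, p_rand = NA_real_,
                 n = nrow(dat), df_resid = dfres,
                 subgroup_prevalence = NA_real_),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("%s: beta = %.4g [%.4g, %.4g], p = %.3g, n = %d\n",
              x$term, x$beta, x$ci_low, x$ci_high, x$p_model, x$n))
  invisible(x)
}

#' Collect association results into a data frame
#' @param results a list of `association_result` objects.
#' @return a data frame, one row per result (forest-plot ready).
#' @export
association_table <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    data.frame(term = r$term, beta = r$beta, se = r$se, ci_low = r$ci_low,
               ci_high = r$ci_high, p_model = r$p_model, p_fdr = r$p_fdr,
               p_rand = r$p_rand, n = r$n,
               subgroup_prevalence = r$subgroup_prevalence,
               stringsAsFactors = FALSE)
  }))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment via [stats::p.adjust()]:
#' monotone, capped at 1, order-preserving under the original indexing.
#'
#' @param pvalues numeric vector in \[0, 1\].
#' @return adjusted p-values in the original order.
#' @export
bh_fdr <- function(pvalues) {
  if (!is.numeric(pvalues) || any(is.na(pvalues)) ||
      any(pvalues < 0 | pvalues > 1)) {
    mc_user_error("p-values must be numeric in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' Screen every exposure (and microbe presence) against the outcome
#'
#' One covariate-adjusted linear model per exposure; Benjamini-Hochberg FDR
#' is applied across the family of exposure tests (the microbe-presence row
#' is reported alongside but is not part of that family).
#'
#' @inheritParams fit_adjusted
#' @param scale_per_sd if `TRUE`, exposures are standardized so betas are
#'   per-SD.
#' @return a data frame of association results with `p_fdr` filled in for
#'   the exposure rows.
#' @export
screen_all <- function(table, covariates = covariate_names(), weights = NULL,
                       outcome = "log_tcdi", scale_per_sd = FALSE) {
  stopifnot(inherits(table, "cohort_table"))
  expos <- exposures_of(table)
  res <- lapply(expos, function(e) {
    z <- table[[e]]
    if (scale_per_sd) z <- z / sd(z)
    tryCatch(
      fit_adjusted(table, z, outcome = outcome, covariates = covariates,
                   weights = weights, term_name = e),
      error = function(err) {
        stop(sprintf("screen_all failed for exposure '%s': %s",
                     e, conditionMessage(err)), call. = FALSE)
      })
  })
  padj <- bh_fdr(vapply(res, `[[`, 0, "p_model"))
  for (i in seq_along(res)) res[[i]]$p_fdr <- padj[i]
  microbe <- fit_adjusted(table, "microbe_present", outcome = outcome,
                          covariates = covariates, weights = weights)
  association_table(c(res, list(microbe)))
}
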