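# Covariate-balanced inference for a thresholded clique, effect
# modification by microbe presence, and randomization-based p-values.

#' Randomization-based p-value for a regression coefficient
#'
#' Permutes the outcome vector only (design, covariates and weights stay
#' fixed), recomputes the focal |t| each time, and reports the add-one
#' corrected tail frequency `(1 + #{|t_perm| >= |t_obs|}) / (1 + B)`; the
#' smallest attainable value is `1/(B+1)`.
#'
#' @param table a `cohort_table`.
#' @param term focal column name or numeric vector.
#' @param outcome outcome column.
#' @param covariates covariate columns.
#' @param weights optional positive regression weights.
#' @param n_permutations number of permutations (>= 99).
#' @param seed integer seed.
#' @return the randomization p-value, with attribute `t_obs`.
#' @export
permutation_pvalue <- function(table, term, outcome = "log_tcdi",
                               covariates = covariate_names(),
                               weights = NULL, n_permutations = 10000,
                               seed = 1L) {
  if (n_permutations < 99) mc_user_error("n_permutations must be >= 99")
  df <- as.data.frame(table)
  z <- if (is.character(term) && length(term) == 1) df[[term]] else as.numeric(term)
  y <- df[[outcome]]
  n <- length(y)
  df <- droplevels(df)
  covariates <- covariates[vapply(covariates, function(cl) {
    !(is.factor(df[[cl]]) && nlevels(df[[cl]]) < 2)
  }, TRUE)]
  C <- model.matrix(
    as.formula(paste("~", if (length(covariates))
      paste(covariates, collapse = " + ") else "1")), data = df)
  sw <- if (is.null(weights)) rep(1, n) else sqrt(weights)
  qrC <- qr(C * sw)
  rz <- qr.resid(qrC, z * sw)
  denom <- sum(rz^2)
  if (denom < 1e-10) mc_user_error("focal term is collinear with covariates")
  df_resid <- n - ncol(C) - 1
  tstat <- function(RY) {
    beta <- as.vector(crossprod(rz, RY)) / denom
    rss <- colSums(RY^2) - beta^2 * denom
    beta / sqrt(pmax(rss, 0) / df_resid / denom)
  }
  t_obs <- tstat(matrix(qr.resid(qrC, y * sw), ncol = 1))
  hits <- 0L
  done <- 0L
  with_seed(seed, {
    while (done < n_permutations) {
      b <- min(2000L, n_permutations - done)
      P <- vapply(seq_len(b), function(i) y[sample.int(n)], numeric(n))
      RY <- qr.resid(qrC, P * sw)
      tp <- tstat(RY)
      hits <- hits + sum(abs(tp) >= abs(t_obs) - 1e-12)
      done <- done + b
    }
  })
  p <- (1 + hits) / (1 + n_permutations)
  attr(p, "t_obs") <- as.vector(t_obs)
  p
}

#' Association of a thresholded clique with the outcome
#'
#' Weighted least squares of the (log-scale) outcome on the clique's binary
#' indicator plus covariates.
#'
#' @param table a `cohort_table`.
#' @param clique a `thresholded_clique`.
#' @param weights balancing weights (e.g. from [balance_cohort()]); `NULL`
#'   for unweighted.
#' @param covariates covariate columns.
#' @param outcome outcome column.
#' @param n_permutations if > 0, a randomization p-value is attached.
#' @param seed seed for the permutations.
#' @return an `association_result` with `subgroup_prevalence` filled in.
#' @export
clique_association <- function(table, clique, weights = NULL,
                               covariates = covariate_names(),
                               outcome = "log_tcdi", n_permutations = 0,
                               seed = 1L) {
  ind <- clique_indicator(clique, table)
  if (all(ind == 0) || all(ind == 1)) {
    mc_user_error("degenerate clique indicator (prevalence %g)", mean(ind))
  }
  res <- fit_adjusted(table, ind, outcome = outcome, covariates = covariates,
                      weights = weights, term_name = format(clique))
  res$subgroup_prevalence <- mean(ind)
  if (n_permutations > 0) {
    res$p_rand <- as.vector(permutation_pvalue(
      table, ind, outcome = outcome, covariates = covariates,
      weights = weights, n_permutations = n_permutations, seed = seed))
  }
  res
}

#' Effect modification of the clique association by microbe presence
#'
#' Stratified mode fits the covariate-adjusted clique model separately in
#' microbe-absent and microbe-present children; interaction mode fits one
#' model with a clique-by-microbe product term.  Stratum prevalences are
#' reported relative to the full sample, so they sum to the overall clique
#' prevalence.  A stratum in which the indicator is degenerate is reported
#' as inestimable (`NULL` result, flag recorded), not silently dropped.
#'
#' @inheritParams clique_association
#' @param microbe binary modifier column, default `"microbe_present"`.
#' @param mode `"stratified"` (headline) or `"interaction"` (formal test).
#' @return an `effect_modification_result`: list with `overall`,
#'   `stratum_absent`, `stratum_present`, `prevalence_absent`,
#'   `prevalence_present`, `inestimable`, and (interaction mode)
#'   `interaction`.
#' @export
effect_modification <- function(table, clique, weights = NULL,
                                covariates = covariate_names(),
                                microbe = "microbe_present",
                                outcome = "log_tcdi",
                                mode = c("stratified", "interaction"),
                                n_permutations = 0, seed = 1L) {
  mode <- match.arg(mode)
  ind <- clique_indicator(clique, table)
  mic <- as.data.frame(table)[[microbe]]
  overall <- clique_association(table, clique, weights, covariates, outcome,
                                n_permutations, seed = fan_out_seed(seed, 1))
  out <- list(
    overall = overall,
    prevalence_absent = mean(ind == 1 & mic == 0),
    prevalence_present = mean(ind == 1 & mic == 1),
    inestimable = character(0),
    mode = mode
  )
  strat_fit <- function(keep, label, counter) {
    sub <- table[keep, , drop = FALSE]
    zi <- ind[keep]
    if (length(unique(zi)) < 2) {
      out$inestimable <<- c(out$inestimable, label)
      return(NULL)
    }
    res <- fit_adjusted(sub, zi, outcome = outcome, covariates = covariates,
                        weights = if (is.null(weights)) NULL else weights[keep],
                        term_name = paste0(format(clique), " | ", label))
    res$subgroup_prevalence <- mean(zi)
    if (n_permutations > 0) {
      res$p_rand <- as.vector(permutation_pvalue(
        sub, zi, outcome = outcome, covariates = covariates,
        weights = if (is.null(weights)) NULL else weights[keep],
        n_permutations = n_permutations, seed = fan_out_seed(seed, counter)))
    }
    res
  }
  out$stratum_absent <- strat_fit(mic == 0, "microbe absent", 2L)
  out$stratum_present <- strat_fit(mic == 1, "microbe present", 3L)
  if (mode == "interaction") {
    df <- as.data.frame(table)
    dat <- data.frame(.y = df[[outcome]], .z = ind, .m = mic,
                      df[, covariates, drop = FALSE])
    dat <- droplevels(dat)
    fml <- as.formula(paste(".y ~ .z * .m",
                            if (length(covariates))
                              paste("+", paste(covariates, collapse = " + "))
                            else ""))
    fit <- if (is.null(weights)) lm(fml, data = dat) else {
      dat$.w <- weights
      lm(fml, data = dat, weights = .w)
    }
    cf <- summary(fit)$coefficients
    if (!".z:.m" %in% rownames(cf)) {
      out$inestimable <- c(out$inestimable, "interaction")
    } else {
      est <- cf[".z:.m", ]
      half <- qt(0.975, fit$df.residual) * est["Std. Error"]
      out$interaction <- structure(list(
        term = "clique x microbe", beta = unname(est["Estimate"]),
        se = unname(est["Std. Error"]),
        ci_low = unname(est["Estimate"] - half),
        ci_high = unname(est["Estimate"] + half),
        t = unname(est["t value"]), p_model = unname(est["Pr(>|t|)"]),
        p_fdr = NA_real_, p_rand = NA_real_, n = nrow(dat),
        df_resid = fit$df.residual, subgroup_prevalence = mean(ind)),
        class = "association_result")
    }
  }
  class(out) <- "effect_modification_result"
  out
}

#' @export
print.effect_modification_result <- function(x, ...) {
  cat("Overall: "); print(x$overall)
  if (!is.null(x$stratum_absent)) { cat("Absent : "); print(x$stratum_absent) }
  if (!is.null(x$stratum_present)) { cat("Present: "); print(x$stratum_present) }
  if (!is.null(x$interaction)) { cat("Interac: "); print(x$interaction) }
  if (length(x$inestimable)) cat("Inestimable:", x$inestimable, "\n")
  invisible(x)
}

#' Logistic association on the odds-ratio scale
#'
#' Shared engine for the binarized-outcome and negative-control analyses.
#' With balancing weights the model is fitted as quasibinomial (non-integer
#' weighted likelihood).  (Quasi-)separation is flagged; with
#' `penalize = TRUE` a ridge-stabilized refit provides the point estimate
#' (no CI).
#' @noRd
logistic_or <- function(ybin, z, df, covariates, weights, term_name,
                        penalize = FALSE) {
  if (length(unique(ybin)) < 2) mc_user_error("degenerate binary outcome")
  dat <- droplevels(data.frame(.y = ybin, .z = z,
                               df[, covariates, drop = FALSE]))
  fml <- as.formula(paste(".y ~ .z",
                          if (length(covariates))
                            paste("+", paste(covariates, collapse = " + "))
                          else ""))
  fam <- if (is.null(weights)) binomial() else quasibinomial()
  fit <- suppressWarnings(
    if (is.null(weights)) glm(fml, family = fam, data = dat)
    else { dat$.w <- weights; glm(fml, family = fam, data = dat, weights = .w) })
  sep <- any(fitted(fit) < 1e-8) || any(fitted(fit) > 1 - 1e-8) ||
    abs(coef(fit)[".z"]) > 15
  cf <- summary(fit)$coefficients
  b <- cf[".z", "Estimate"]; se <- cf[".z", "Std. Error"]
  p <- cf[".z", ncol(cf)]
  if (sep) {
    warning("(quasi-)separation in logistic fit", call. = FALSE)
    if (penalize) {
      b <- ridge_logistic_coef(fml, dat, weights)
      se <- NA_real_; p <- NA_real_
    }
  }
  structure(list(term = term_name, or = exp(b), beta = b, se = se,
                 ci_low = exp(b - 1.96 * se), ci_high = exp(b + 1.96 * se),
                 p_model = p, n = nrow(dat), separation = sep),
            class = "or_result")
}

# ridge-stabilized logistic point estimate (IRLS with small L2 penalty on
# the non-intercept coefficients)
#' @noRd
ridge_logistic_coef <- function(fml, dat, weights, lambda = 0.5) {
  X <- model.matrix(fml, data = dat)
  y <- dat$.y
  w0 <- if (is.null(weights)) rep(1, nrow(X)) else weights
  beta <- setNames(rep(0, ncol(X)), colnames(X))
  pen <- diag(lambda, ncol(X)); pen[1, 1] <- 0
  for (i in 1:50) {
    eta <- as.vector(X %*% beta)
    mu <- plogis(eta)
    W <- w0 * mu * (1 - mu)
    score <- crossprod(X, w0 * (y - mu)) - pen %*% beta
    info <- crossprod(X, X * W) + pen
    step <- as.vector(solve(info, score))
    beta <- beta + step
    if (max(abs(step)) < 1e-8) break
  }
  unname(beta[".z"])
}

#' @export
print.or_result <- function(x, ...) {
  cat(sprintf("%s: OR = %.3g [%.3g, %.3g], p = %.3g, n = %d%s\n",
              x$term, x$or, x$ci_low, x$ci_high, x$p_model, x$n,
              if (isTRUE(x$separation)) " [separation]" else ""))
  invisible(x)
}

#' Clique association with a binarized outcome
#'
#' Dichotomizes the t-scored outcome at a sample percentile (default the
#' 75th) and fits a weighted logistic regression of the high-symptom
#' indicator on the clique plus covariates.
#'
#' @inheritParams clique_association
#' @param threshold_percentile sample percentile defining the high-outcome
#'   class.
#' @param penalize use a ridge-stabilized refit if separation occurs.
#' @return an `or_result` (odds-ratio scale).
#' @export
binarized_outcome_analysis <- function(table, clique,
                                       threshold_percentile = 75,
                                       weights = NULL,
                                       covariates = covariate_names(),
                                       penalize = FALSE) {
  df <- as.data.frame(table)
  cut <- mc_quantile(df$tcdi, threshold_percentile / 100)
  ybin <- as.integer(df$tcdi >= cut)
  z <- clique_indicator(clique, table)
  logistic_or(ybin, z, df, covariates, weights,
              sprintf("tCDI >= p%g ~ %s", threshold_percentile,
                      format(clique)), penalize)
}

#' Negative-control outcome analysis
#'
#' Logistic regression of pet ownership (an outcome that cannot plausibly
#' be caused by prenatal metal exposure) on the clique indicator plus
#' covariates.  A CI covering 1 is labelled consistent with no association;
#' anything else points at selection or residual confounding.
#'
#' @inheritParams binarized_outcome_analysis
#' @return an `or_result` with an extra `consistent_with_null` flag.
#' @export
negative_control <- function(table, clique, weights = NULL,
                             covariates = covariate_names(),
                             penalize = FALSE) {
  df <- as.data.frame(table)
  if (is.null(df$pet)) mc_user_error("pet column (negative control) not found")
  z <- clique_indicator(clique, table)
  res <- logistic_or(df$pet, z, df, covariates, weights,
                     paste("pet ~", format(clique)), penalize)
  res$consistent_with_null <- !is.na(res$ci_low) &&
    res$ci_low <= 1 && res$ci_high >= 1
  res
}
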