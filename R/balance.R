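# Propensity-score subclassification and balance diagnostics.
#
# Covariate balance between microbe-present and microbe-absent children is
# obtained by stratifying on the estimated propensity score and weighting
# the strata (marginal mean weighting through stratification): within
# subclass s, members of group g receive weight (n_s / N) * (N_g / n_{s,g}),
# which preserves each group's total size while equalizing the subclass
# composition across groups.  Standardized mean differences before/after
# weighting are the love-plot diagnostic.

#' Estimate propensity scores for group membership
#'
#' Logistic regression of the binary group on all covariates.
#'
#' @param table a `cohort_table` with complete covariates.
#' @param covariates covariate columns.
#' @param group binary group column, default `"microbe_present"`.
#' @return fitted probabilities in (0,1).
#' @export
estimate_propensity <- function(table, covariates = covariate_names(),
                                group = "microbe_present") {
  df <- as.data.frame(table)
  g <- df[[group]]
  if (length(unique(g)) < 2) mc_user_error("both groups must be nonempty")
  dat <- data.frame(.g = g, df[, covariates, drop = FALSE])
  if (anyNA(dat)) mc_user_error("missing covariate cells; impute first")
  fit <- suppressWarnings(
    glm(as.formula(paste(".g ~", paste(covariates, collapse = " + "))),
        family = binomial(), data = dat))
  p <- fitted(fit)
  if (any(p < 1e-10) || any(p > 1 - 1e-10)) {
    mc_user_error(paste("(quasi-)perfect separation in the propensity model;",
                        "use fewer covariates or penalization"))
  }
  as.vector(p)
}

#' Subclassify on the propensity score and compute balancing weights
#'
#' Subclasses are cut at propensity quantiles.  A subclass missing one of
#' the groups is merged with its neighboring subclass toward the median
#' propensity (logged via message); if fewer than 2 usable subclasses
#' remain, an error is raised.
#'
#' @param propensity fitted propensities.
#' @param group 0/1 group vector.
#' @param n_subclasses requested number of subclasses (>= 2).
#' @return list with `subclass` (integer labels 1..S after merging),
#'   `weight` (positive; weighted group totals equal unweighted group
#'   sizes), and `n_subclasses_used`.
#' @export
subclassify <- function(propensity, group, n_subclasses = 6) {
  stopifnot(length(propensity) == length(group))
  if (n_subclasses < 2) mc_user_error("n_subclasses must be >= 2")
  N <- length(group)
  breaks <- unique(mc_quantile(propensity, seq(0, 1, length.out = n_subclasses + 1)))
  if (length(breaks) < 3) mc_user_error("propensity too degenerate to subclassify")
  sub <- as.integer(cut(propensity, breaks, include.lowest = TRUE))

  repeat {
    tab <- table(factor(sub, levels = sort(unique(sub))), group)
    bad <- rownames(tab)[tab[, 1] == 0 | tab[, 2] == 0]
    if (length(bad) == 0) break
    levels_now <- sort(unique(sub))
    if (length(levels_now) <= 2) {
      if (length(bad) > 0 && length(levels_now) - length(bad) < 1) {
        mc_user_error("fewer than 2 usable subclasses after merging")
      }
    }
    s <- as.integer(bad[1])
    pos <- match(s, levels_now)
    # merge toward the median-propensity (middle) subclass
    target <- if (pos <= length(levels_now) / 2) levels_now[pos + 1]
              else levels_now[pos - 1]
    if (is.na(target)) mc_user_error("fewer than 2 usable subclasses after merging")
    message(sprintf("subclassify: merging subclass %d into %d (empty group)",
                    s, target))
    sub[sub == s] <- target
    if (length(unique(sub)) < 2) {
      mc_user_error("fewer than 2 usable subclasses after merging")
    }
  }
  sub <- match(sub, sort(unique(sub)))   # relabel 1..S
  w <- numeric(N)
  for (s in sort(unique(sub))) {
    in_s <- sub == s
    n_s <- sum(in_s)
    for (g in c(0, 1)) {
      n_sg <- sum(in_s & group == g)
      N_g <- sum(group == g)
      w[in_s & group == g] <- (n_s / N) * (N_g / n_sg)
    }
  }
  list(subclass = sub, weight = w, n_subclasses_used = length(unique(sub)))
}

#' Standardized mean differences between groups
#'
#' Per covariate (factors expanded to one indicator per level):
#' (weighted mean difference) / pooled SD, where the pooled SD is the
#' unweighted full-sample pooled group SD, `sqrt((s1^2 + s0^2) / 2)` -- the
#' denominator is fixed so before/after SMDs share a scale.  A covariate
#' with zero pooled SD reports SMD 0 and is flagged in attribute
#' `zero_variance`.
#'
#' @param table a `cohort_table` (or data frame).
#' @param group 0/1 vector or the name of a binary column.
#' @param weights optional balancing weights.
#' @param covariates covariate columns.
#' @return named numeric vector of SMDs.
#' @export
standardized_mean_differences <- function(table, group = "microbe_present",
                                          weights = NULL,
                                          covariates = covariate_names()) {
  df <- as.data.frame(table)
  g <- if (is.character(group) && length(group) == 1) df[[group]] else group
  X <- covariate_design(df, covariates)
  if (is.null(weights)) weights <- rep(1, nrow(X))
  wmean <- function(x, w) sum(x * w) / sum(w)
  out <- numeric(ncol(X)); zerov <- logical(ncol(X))
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    s2 <- (var(x[g == 1]) + var(x[g == 0])) / 2
    d <- wmean(x[g == 1], weights[g == 1]) - wmean(x[g == 0], weights[g == 0])
    if (is.na(s2) || s2 == 0) { out[j] <- 0; zerov[j] <- TRUE }
    else out[j] <- d / sqrt(s2)
  }
  names(out) <- colnames(X)
  attr(out, "zero_variance") <- colnames(X)[zerov]
  out
}

#' @noRd
covariate_design <- function(df, covariates) {
  cols <- lapply(covariates, function(cl) {
    x <- df[[cl]]
    if (is.factor(x) || is.character(x)) {
      x <- factor(x)
      M <- vapply(levels(x), function(lv) as.numeric(x == lv),
                  numeric(length(x)))
      colnames(M) <- paste0(cl, "_", levels(x))
      M
    } else {
      M <- matrix(as.numeric(x), ncol = 1)
      colnames(M) <- cl
      M
    }
  })
  do.call(cbind, cols)
}

#' Balance a cohort on the microbe indicator
#'
#' Convenience wrapper: propensity estimation, subclassification, weights,
#' and before/after standardized mean differences.
#'
#' @inheritParams estimate_propensity
#' @param n_subclasses passed to [subclassify()].
#' @return an object of class `balance_result`: list with `propensity`,
#'   `subclass`, `weight`, `smd_before`, `smd_after`, `n_subclasses_used`.
#' @export
balance_cohort <- function(table, covariates = covariate_names(),
                           group = "microbe_present", n_subclasses = 6) {
  p <- estimate_propensity(table, covariates, group)
  g <- as.data.frame(table)[[group]]
  sc <- subclassify(p, g, n_subclasses)
  structure(list(
    propensity = p, subclass = sc$subclass, weight = sc$weight,
    smd_before = standardized_mean_differences(table, group,
                                               covariates = covariates),
    smd_after = standardized_mean_differences(table, group, sc$weight,
                                              covariates = covariates),
    n_subclasses_used = sc$n_subclasses_used
  ), class = "balance_result")
}

#' Love-plot table of a balance result
#' @param balance a `balance_result`.
#' @return data frame `covariate`, `smd_before`, `smd_after`.
#' @export
love_table <- function(balance) {
  stopifnot(inherits(balance, "balance_result"))
  data.frame(covariate = names(balance$smd_before),
             smd_before = as.vector(balance$smd_before),
             smd_after = as.vector(balance$smd_after),
             stringsAsFactors = FALSE)
}
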