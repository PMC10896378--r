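# Chained-equation imputation by predictive mean matching (PMM).
#
# Missing covariate cells are filled with *observed donor values*: for each
# incomplete column, a linear predictive model is fitted on the observed
# rows, every row is scored, and each missing cell receives the value of one
# of the k observed donors whose predicted values are nearest to the missing
# row's prediction (drawn uniformly among the k).  Columns are visited in
# turn for a fixed number of chained iterations, so each column's model sees
# the current completed values of the others.  Because donors are observed
# values, imputations always lie in the observed support of the column.

#' Impute missing covariates by chained-equation PMM
#'
#' @param table a `cohort_table`; missingness must be confined to numeric
#'   covariates, each less than 50% missing.
#' @param n_chains number of independent chains; the first chain's completed
#'   table is returned (no pooling across chains), the rest are attached as
#'   attribute `chains`.
#' @param n_iterations chained-equation sweeps per chain.
#' @param k_donors donor pool size.
#' @param seed integer; the procedure is seed-deterministic.
#' @return the completed `cohort_table` (zero missing covariate cells).
#' @export
pmm_impute <- function(table, n_chains = 1, n_iterations = 5, k_donors = 5,
                       seed = 1L) {
  stopifnot(inherits(table, "cohort_table"), k_donors >= 1, n_iterations >= 1)
  covs <- covariate_names()
  targets <- covs[vapply(covs, function(cl) anyNA(table[[cl]]), TRUE)]
  other <- setdiff(names(table), covs)
  bad <- other[vapply(other, function(cl) anyNA(table[[cl]]), TRUE)]
  if (length(bad)) {
    mc_user_error("missingness outside the imputable covariates: %s",
                  paste(bad, collapse = ", "))
  }
  if (length(targets) == 0) return(table)
  for (cl in targets) {
    frac <- mean(is.na(table[[cl]]))
    if (frac == 1) mc_user_error("column '%s' is entirely missing", cl)
    if (frac >= 0.5) {
      mc_user_error("column '%s' is %.0f%% missing (>= 50%%)", cl, 100 * frac)
    }
    if (!is.numeric(table[[cl]])) {
      mc_user_error("PMM imputation supports numeric covariates only ('%s')", cl)
    }
  }
  chains <- lapply(seq_len(n_chains), function(ch) {
    with_seed(fan_out_seed(seed, ch), {
      pmm_one_chain(table, targets, n_iterations, k_donors)
    })
  })
  out <- chains[[1]]
  if (n_chains > 1) attr(out, "chains") <- chains[-1]
  out
}

#' @noRd
pmm_one_chain <- function(table, targets, n_iterations, k_donors) {
  obs_idx <- lapply(targets, function(cl) which(!is.na(table[[cl]])))
  mis_idx <- lapply(targets, function(cl) which(is.na(table[[cl]])))
  names(obs_idx) <- names(mis_idx) <- targets
  filled <- table
  # initialize missing cells with random observed values of the same column
  for (cl in targets) {
    filled[[cl]][mis_idx[[cl]]] <-
      sample(table[[cl]][obs_idx[[cl]]], length(mis_idx[[cl]]), replace = TRUE)
  }
  preds_for <- function(cl) {
    setdiff(c(covariate_names(), "log_tcdi", "microbe_present"), cl)
  }
  for (iter in seq_len(n_iterations)) {
    for (cl in targets) {
      rhs <- paste(preds_for(cl), collapse = " + ")
      X <- model.matrix(as.formula(paste("~", rhs)), data = filled)
      yobs <- table[[cl]][obs_idx[[cl]]]
      fit <- stats::lm.fit(X[obs_idx[[cl]], , drop = FALSE], yobs)
      beta <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
      yhat <- as.vector(X %*% beta)
      for (i in mis_idx[[cl]]) {
        d <- abs(yhat[obs_idx[[cl]]] - yhat[i])
        donors <- order(d, seq_along(d))[seq_len(min(k_donors, length(d)))]
        pick <- if (length(donors) == 1) donors else sample(donors, 1)
        filled[[cl]][i] <- yobs[pick]
      }
    }
  }
  filled
}
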