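# Consolidated sensitivity analyses for a fitted clique association.
#
# The suite re-examines the headline estimates from six angles:
#  (1) randomization p-values for the major associations,
#  (2) a note on the deliberately minimal covariate set,
#  (3) the microbe association refitted without balancing weights,
#  (4) all thresholds shifted by +/- a fixed number of percentiles, with a
#      directionality-preservation table,
#  (5) the outcome binarized at a sample percentile and refitted as a
#      logistic model,
#  (6) the negative-control outcome (pet ownership).
# Items fail independently: an error in one is recorded and the suite
# continues.

#' Options for [run_sensitivity_suite()]
#'
#' @param items subset of 1:6 to run; omitted items are marked "skipped".
#' @param n_permutations permutations for item 1 (the full-scale analysis
#'   uses 1e6; the default keeps interactive runs fast).
#' @param perturb_delta percentile shift for item 4.
#' @param binarize_percentile outcome percentile cut for item 5.
#' @param seed integer seed.
#' @return a list of class `sensitivity_config`.
#' @export
sensitivity_config <- function(items = 1:6, n_permutations = 10000,
                               perturb_delta = 10, binarize_percentile = 75,
                               seed = 1L) {
  structure(list(items = items, n_permutations = n_permutations,
                 perturb_delta = perturb_delta,
                 binarize_percentile = binarize_percentile,
                 seed = seed), class = "sensitivity_config")
}

#' Run the full sensitivity suite
#'
#' @param table a `cohort_table` (imputed).
#' @param clique the fitted `thresholded_clique`.
#' @param weights balancing weights used in the main analysis.
#' @param covariates covariate columns.
#' @param config a [sensitivity_config()].
#' @return a list of class `sensitivity_report`; each item has a `status`
#'   (`"ok"`, `"skipped"`, or `"error"`) plus its results.
#' @export
run_sensitivity_suite <- function(table, clique, weights = NULL,
                                  covariates = covariate_names(),
                                  config = sensitivity_config()) {
  run_item <- function(id, fn) {
    if (!id %in% config$items) return(list(status = "skipped"))
    tryCatch(c(list(status = "ok"), fn()),
             error = function(e) list(status = "error",
                                      message = conditionMessage(e)))
  }
  em0 <- effect_modification(table, clique, weights, covariates)
  report <- list(
    randomization = run_item(1, function() {
      list(
        microbe = as.vector(permutation_pvalue(
          table, "microbe_present", weights = weights,
          covariates = covariates,
          n_permutations = config$n_permutations,
          seed = fan_out_seed(config$seed, 11))),
        clique_overall = as.vector(permutation_pvalue(
          table, clique_indicator(clique, table), weights = weights,
          covariates = covariates,
          n_permutations = config$n_permutations,
          seed = fan_out_seed(config$seed, 12)))
      )
    }),
    minimal_covariates = run_item(2, function() {
      list(note = paste("models adjust for a deliberately minimal covariate",
                        "set; covariate balancing provides the additional",
                        "confounding control"),
           covariates = covariates)
    }),
    unbalanced_microbe = run_item(3, function() {
      r <- fit_adjusted(table, "microbe_present", covariates = covariates)
      list(result = unclass(r))
    }),
    threshold_perturbation = run_item(4, function() {
      base_signs <- c(overall = sign(em0$overall$beta),
                      absent = if (is.null(em0$stratum_absent)) NA
                               else sign(em0$stratum_absent$beta),
                      present = if (is.null(em0$stratum_present)) NA
                                else sign(em0$stratum_present$beta))
      rows <- list()
      for (delta in c(-config$perturb_delta, config$perturb_delta)) {
        pc <- perturb_thresholds(clique, delta)
        em <- effect_modification(table, pc, weights, covariates)
        betas <- c(overall = em$overall$beta,
                   absent = if (is.null(em$stratum_absent)) NA
                            else em$stratum_absent$beta,
                   present = if (is.null(em$stratum_present)) NA
                             else em$stratum_present$beta)
        rows[[length(rows) + 1]] <- data.frame(
          delta = delta, term = names(betas), beta = unname(betas),
          same_sign = unname(sign(betas) == base_signs),
          stringsAsFactors = FALSE)
      }
      tab <- do.call(rbind, rows)
      list(table = tab,
           directionality_preserved = all(tab$same_sign, na.rm = TRUE))
    }),
    binarized_outcome = run_item(5, function() {
      r <- binarized_outcome_analysis(table, clique,
                                      config$binarize_percentile, weights,
                                      covariates)
      list(result = unclass(r))
    }),
    negative_control = run_item(6, function() {
      r <- negative_control(table, clique, weights, covariates)
      list(result = unclass(r))
    })
  )
  structure(c(report, list(clique = format(clique),
                           main = list(
                             overall = unclass(em0$overall),
                             stratum_absent = if (!is.null(em0$stratum_absent))
                               unclass(em0$stratum_absent),
                             stratum_present = if (!is.null(em0$stratum_present))
                               unclass(em0$stratum_present),
                             prevalence_absent = em0$prevalence_absent,
                             prevalence_present = em0$prevalence_present))),
            class = "sensitivity_report")
}

#' Write a sensitivity report as JSON (plus a TSV of the perturbation table)
#'
#' @param report a `sensitivity_report`.
#' @param dir output directory (created if needed).
#' @return the JSON path, invisibly.
#' @export
write_sensitivity_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, "sensitivity.json")
  jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, force = TRUE)
  tp <- report$threshold_perturbation
  if (identical(tp$status, "ok")) {
    write.table(tp$table, file.path(dir, "threshold_perturbation.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
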