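# Descriptive statistics and correlation structure.

#' Two-sided Fisher exact test for a 2 x k contingency table
#'
#' Thin, validating wrapper around [stats::fisher.test()]: conditional on
#' the observed margins, the two-sided p-value sums the probabilities of all
#' tables at most as probable as the observed one (the usual convention;
#' Freeman-Halton extension for k > 2).
#'
#' @param counts an integer matrix of non-negative counts, at least 2 x 2.
#' @return the two-sided p-value.
#' @export
fisher_exact <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2 || ncol(counts) < 2) {
    mc_user_error("fisher_exact needs at least a 2 x 2 table")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    mc_user_error("counts must be non-negative integers")
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    mc_user_error("fisher_exact: a margin of the table is zero")
  }
  fisher.test(counts)$p.value
}

#' Wilcoxon rank-sum p-value for a continuous variable across two strata
#'
#' Exact enumeration for small, tie-free samples; normal approximation with
#' continuity correction otherwise (the [stats::wilcox.test()] rules).
#' @noRd
wilcoxon_p <- function(x, g) {
  ok <- !is.na(x)
  if (length(unique(x[ok])) <= 1) return(1)   # no rank information at all
  p <- suppressWarnings(wilcox.test(x ~ g)$p.value)
  if (is.nan(p)) 1 else p
}

#' Cohort descriptive statistics, stratified by microbe presence
#'
#' One row per variable (or level): `mean (SD)` for continuous variables with
#' a Wilcoxon rank-sum p-value across strata, `n (%)` for categorical
#' variables with a Fisher exact p-value.
#'
#' @param table a `cohort_table` (missing covariate cells are omitted from
#'   the summaries).
#' @param strata stratifying binary column, default `"microbe_present"`.
#' @return a data frame with columns `variable`, `level`, `overall`,
#'   `stratum0`, `stratum1`, `p_value`, plus numeric helper columns.
#' @export
descriptives <- function(table, strata = "microbe_present") {
  stopifnot(inherits(table, "cohort_table"))
  g <- table[[strata]]
  if (length(unique(g)) < 2 || min(table(g)) == 0) {
    mc_user_error("stratum with zero members")
  }
  rows <- list()
  fmt_mean <- function(x) sprintf("%.1f (%.1f)", mean(x, na.rm = TRUE),
                                  sd(x, na.rm = TRUE))
  add_cont <- function(var) {
    x <- table[[var]]
    p <- wilcoxon_p(x, g)
    rows[[length(rows) + 1]] <<- data.frame(
      variable = var, level = "", overall = fmt_mean(x),
      stratum0 = fmt_mean(x[g == 0]), stratum1 = fmt_mean(x[g == 1]),
      p_value = p, stringsAsFactors = FALSE)
  }
  add_cat <- function(var) {
    x <- factor(table[[var]])
    tab <- table(x, g)
    p <- fisher_exact(tab)
    for (lv in levels(x)) {
      n_all <- sum(x == lv, na.rm = TRUE)
      n0 <- sum(x == lv & g == 0, na.rm = TRUE)
      n1 <- sum(x == lv & g == 1, na.rm = TRUE)
      fmt <- function(k, N) sprintf("%d (%.1f)", k, 100 * k / N)
      rows[[length(rows) + 1]] <<- data.frame(
        variable = var, level = lv, overall = fmt(n_all, length(x)),
        stratum0 = fmt(n0, sum(g == 0)), stratum1 = fmt(n1, sum(g == 1)),
        p_value = p, stringsAsFactors = FALSE)
    }
  }
  add_cat("sex"); add_cat("ses")
  add_cont("maternal_age"); add_cont("maternal_bmi"); add_cont("child_age")
  add_cont("tcdi")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Exposure correlation matrix
#'
#' Spearman (mid-rank) correlations between all exposure columns by default;
#' Pearson available.  Pairs with fewer than 3 complete observations, and
#' constant columns, yield `NA` entries with a warning.
#'
#' @param table a `cohort_table` (or data frame restricted to exposures).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return a symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(table, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  cols <- if (inherits(table, "cohort_table")) exposures_of(table) else names(table)
  X <- as.matrix(as.data.frame(table)[, cols, drop = FALSE])
  const <- apply(X, 2, function(x) length(unique(x[!is.na(x)])) <= 1)
  n_pairs <- crossprod(!is.na(X))
  if (any(n_pairs < 3)) {
    warning("correlation_matrix: pair(s) with fewer than 3 complete observations set to NA")
  }
  if (any(const)) {
    warning(sprintf("correlation_matrix: constant column(s) set to NA: %s",
                    paste(cols[const], collapse = ", ")))
  }
  suppressWarnings(R <- cor(X, method = method, use = "pairwise.complete.obs"))
  R[n_pairs < 3] <- NA
  R[const, ] <- NA
  R[, const] <- NA
  diag(R)[!const] <- 1
  R
}
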