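# Quantile-based threshold finding.
#
# A discovered signature fixes *which* exposures and *which* sides; the
# threshold search fixes *where*.  Every combination of percentile
# thresholds on a grid (one percentile per member) induces a candidate
# binary subgroup; among candidates whose prevalence stays inside
# configurable bounds, the search returns the one maximizing the absolute
# t-statistic of the indicator in the covariate-adjusted regression of the
# outcome.  The search is exhaustive and deterministic; ties break toward
# thresholds nearest the 50th percentile, then lexicographically.

#' Find percentile thresholds for a clique signature
#'
#' @param signature signed features: a character vector like
#'   `c("Zn_T2+", "Co_T3-")`, a single `" & "`-joined string, or a
#'   `thresholded_clique` (whose percentiles are ignored).
#' @param table a `cohort_table` with complete model variables.
#' @param covariates covariate columns for the adjusted model.
#' @param outcome outcome column, default `"log_tcdi"`.
#' @param grid percentile grid searched per member (default 5 to 95 by 5).
#' @param prevalence_bounds admissible subgroup prevalence `(lo, hi)`,
#'   bounds within (0,1).
#' @param weights optional positive regression weights.
#' @param max_candidates guard on the grid size `length(grid)^order`.
#' @return a `thresholded_clique` with attributes `t_stat`, `beta`,
#'   `prevalence`, `n_candidates`, `n_admissible`.
#' @export
find_thresholds <- function(signature, table,
                            covariates = covariate_names(),
                            outcome = "log_tcdi",
                            grid = seq(5, 95, by = 5),
                            prevalence_bounds = c(0.05, 0.95),
                            weights = NULL,
                            max_candidates = 2e5) {
  if (inherits(signature, "thresholded_clique")) {
    signature <- clique_signature(signature)
  } else if (is.character(signature) && length(signature) == 1 &&
             grepl("&", signature)) {
    signature <- trimws(strsplit(signature, "&", fixed = TRUE)[[1]])
  }
  validate_signed_features(signature)
  if (length(grid) == 0) mc_user_error("percentile grid is empty")
  if (any(grid <= 0) || any(grid >= 100)) {
    mc_user_error("grid percentiles must lie strictly in (0, 100)")
  }
  lo <- prevalence_bounds[1]; hi <- prevalence_bounds[2]
  if (lo <= 0 || hi >= 1 || lo >= hi) {
    mc_user_error("prevalence bounds must satisfy 0 < lo < hi < 1")
  }
  sf <- split_signed(signature)
  m <- nrow(sf)
  missing_cols <- setdiff(sf$exposure, names(table))
  if (length(missing_cols)) {
    mc_user_error("exposure column(s) missing from table: %s",
                  paste(missing_cols, collapse = ", "))
  }
  n <- nrow(table)
  g <- length(grid)
  if (g^m > max_candidates) {
    mc_user_error("grid too large: %d^%d candidates; coarsen the grid", g, m)
  }

  # per-member condition matrices (n x g), on the raw (unweighted) scale
  cond <- lapply(seq_len(m), function(i) {
    x <- table[[sf$exposure[i]]]
    qs <- vapply(grid / 100, function(p) mc_quantile(x, p), 0)
    M <- if (sf$sign[i] == "+") outer(x, qs, `>`) else outer(x, qs, `<=`)
    storage.mode(M) <- "double"
    M
  })

  # covariate projection (weighted via sqrt-w transform)
  df <- as.data.frame(table)
  C <- model.matrix(
    as.formula(paste("~", if (length(covariates))
      paste(covariates, collapse = " + ") else "1")), data = df)
  yv <- df[[outcome]]
  if (anyNA(C) || anyNA(yv)) mc_user_error("missing cells in model variables")
  sw <- if (is.null(weights)) rep(1, n) else {
    stopifnot(length(weights) == n, all(weights > 0))
    sqrt(weights)
  }
  qrC <- qr(C * sw)
  ry <- qr.resid(qrC, yv * sw)
  df_resid <- n - ncol(C) - 1
  if (df_resid <= 0) mc_user_error("not enough rows for the adjusted model")

  combos <- as.matrix(expand.grid(rep(list(seq_len(g)), m)))
  best <- NULL
  chunk <- max(1L, floor(2e6 / n))
  for (start in seq(1, nrow(combos), by = chunk)) {
    idx <- start:min(start + chunk - 1, nrow(combos))
    Z <- cond[[1]][, combos[idx, 1], drop = FALSE]
    if (m > 1) for (i in 2:m) Z <- Z * cond[[i]][, combos[idx, i], drop = FALSE]
    prev <- colMeans(Z)
    adm <- prev >= lo & prev <= hi
    if (!any(adm)) next
    Zw <- Z[, adm, drop = FALSE] * sw
    RZ <- qr.resid(qrC, Zw)
    denom <- colSums(RZ^2)
    beta <- as.vector(crossprod(RZ, ry)) / denom
    rss <- sum(ry^2) - beta^2 * denom
    tval <- beta / sqrt(pmax(rss / df_resid, 0) / denom)
    tval[denom < 1e-10] <- NA
    for (j in which(!is.na(tval))) {
      cand <- list(abs_t = abs(tval[j]),
                   pct = grid[combos[idx[which(adm)[j]], ]],
                   beta = beta[j], t = tval[j],
                   prevalence = prev[adm][j])
      if (is.null(best) || better_candidate(cand, best)) best <- cand
    }
  }
  if (is.null(best)) {
    mc_user_error("no admissible candidate: all prevalences outside (%g, %g)",
                  lo, hi)
  }
  out <- thresholded_clique(sf$exposure, sf$sign, best$pct)
  attr(out, "t_stat") <- best$t
  attr(out, "beta") <- best$beta
  attr(out, "prevalence") <- best$prevalence
  attr(out, "n_candidates") <- g^m
  out
}

# strictly better: larger |t|; ties toward thresholds nearest the median,
# then lexicographically smaller percentile vector
#' @noRd
better_candidate <- function(a, b) {
  if (a$abs_t != b$abs_t) return(a$abs_t > b$abs_t)
  da <- sum(abs(a$pct - 50)); db <- sum(abs(b$pct - 50))
  if (da != db) return(da < db)
  for (i in seq_along(a$pct)) {
    if (a$pct[i] != b$pct[i]) return(a$pct[i] < b$pct[i])
  }
  FALSE
}
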