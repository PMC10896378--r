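# Signed features, clique signatures, and thresholded cliques.
#
# A signed feature is an exposure plus the side of a decision split it takes:
# "+" means the high side (concentration above a threshold), "-" the low side.
# A clique signature is an order-free set of signed features; a thresholded
# clique equips each member with a percentile threshold, inducing a binary
# subgroup indicator.

#' Canonical string form of a set of signed features
#'
#' Members are sorted lexicographically (locale-independent radix sort) so
#' that `{Zn_T2+, Co_T3-}` and `{Co_T3-, Zn_T2+}` map to the same string and
#' hash identically.
#'
#' @param members character vector of signed features, e.g. `c("Zn_T2+", "Co_T3-")`.
#' @return a single string, members joined by `" & "`.
#' @export
canonical_signature <- function(members) {
  members <- unique(as.character(members))
  validate_signed_features(members)
  paste(sort(members, method = "radix"), collapse = " & ")
}

#' @noRd
validate_signed_features <- function(members) {
  if (length(members) == 0) return(invisible(members))
  bad <- !grepl("[+-]$", members)
  if (any(bad)) {
    mc_user_error("signed features must end in '+' or '-': %s",
                  paste(members[bad], collapse = ", "))
  }
  expo <- sub("[+-]$", "", members)
  if (anyDuplicated(expo)) {
    mc_user_error("an exposure may appear at most once per signature: %s",
                  paste(expo[duplicated(expo)], collapse = ", "))
  }
  invisible(members)
}

#' Split signed features into exposure names and signs
#' @noRd
split_signed <- function(members) {
  data.frame(
    exposure = sub("[+-]$", "", members),
    sign = substring(members, nchar(members)),
    stringsAsFactors = FALSE
  )
}

#' Construct a thresholded clique
#'
#' A thresholded clique is a set of signed exposures, each with a percentile
#' threshold.  A participant is *in* the induced subgroup iff every "+"
#' member's concentration is strictly greater than that member's sample
#' percentile and every "-" member's concentration is at or below its
#' percentile.  Sample percentiles use the linear-interpolation (type 7)
#' convention throughout.
#'
#' @param exposures character vector of exposure column names (e.g. `"Zn_T2"`).
#' @param signs character vector of `"+"` / `"-"`, one per exposure.
#' @param percentiles numeric vector of percentile thresholds in `[0, 100]`.
#' @return an object of class `thresholded_clique`.
#' @examples
#' thresholded_clique(c("Zn_T2", "Co_T3", "Cr_T2"), c("+", "-", "-"), c(20, 80, 55))
#' @export
thresholded_clique <- function(exposures, signs, percentiles) {
  stopifnot(length(exposures) == length(signs),
            length(signs) == length(percentiles))
  if (!all(signs %in% c("+", "-"))) {
    mc_user_error("signs must be '+' or '-'")
  }
  if (anyDuplicated(exposures)) {
    mc_user_error("an exposure may appear at most once per clique")
  }
  if (length(percentiles) && (any(percentiles < 0) || any(percentiles > 100))) {
    mc_user_error("percentile thresholds must lie in [0, 100]")
  }
  members <- data.frame(
    exposure = as.character(exposures),
    sign = as.character(signs),
    percentile = as.numeric(percentiles),
    stringsAsFactors = FALSE
  )
  members <- members[order(members$exposure, method = "radix"), , drop = FALSE]
  rownames(members) <- NULL
  structure(list(members = members), class = "thresholded_clique")
}

#' @export
format.thresholded_clique <- function(x, ...) {
  m <- x$members
  if (nrow(m) == 0) return("<empty clique>")
  paste(sprintf("%s%s@%g", m$exposure, m$sign, m$percentile), collapse = " & ")
}

#' @export
print.thresholded_clique <- function(x, ...) {
  cat("Thresholded clique:", format(x), "\n")
  invisible(x)
}

#' Parse the compact clique string form
#'
#' Inverse of [format.thresholded_clique()]: `"Zn_T2+@20 & Co_T3-@80"` parses
#' to a two-member clique; round-trips losslessly.
#'
#' @param x a single string.
#' @return a `thresholded_clique`.
#' @export
parse_clique <- function(x) {
  stopifnot(is.character(x), length(x) == 1)
  parts <- trimws(strsplit(x, "&", fixed = TRUE)[[1]])
  m <- regmatches(parts, regexec("^(.*)([+-])@([0-9.]+)$", parts))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) {
    mc_user_error("cannot parse clique member(s): %s",
                  paste(parts[bad], collapse = ", "))
  }
  thresholded_clique(
    exposures = vapply(m, `[`, "", 2L),
    signs = vapply(m, `[`, "", 3L),
    percentiles = as.numeric(vapply(m, `[`, "", 4L))
  )
}

#' Signature (threshold-free) form of a clique
#' @param clique a `thresholded_clique`.
#' @return character vector of signed features.
#' @export
clique_signature <- function(clique) {
  stopifnot(inherits(clique, "thresholded_clique"))
  paste0(clique$members$exposure, clique$members$sign)
}

#' Binary subgroup indicator induced by a thresholded clique
#'
#' @param clique a `thresholded_clique`.
#' @param table a cohort table (or any data frame containing the member
#'   exposure columns).
#' @return integer 0/1 vector with attribute `prevalence` (its mean).  An
#'   empty clique is the vacuous conjunction: all ones.
#' @export
clique_indicator <- function(clique, table) {
  stopifnot(inherits(clique, "thresholded_clique"), is.data.frame(table))
  m <- clique$members
  missing_cols <- setdiff(m$exposure, names(table))
  if (length(missing_cols)) {
    mc_user_error("exposure column(s) missing from table: %s",
                  paste(missing_cols, collapse = ", "))
  }
  ind <- rep(TRUE, nrow(table))
  for (i in seq_len(nrow(m))) {
    x <- table[[m$exposure[i]]]
    q <- mc_quantile(x, m$percentile[i] / 100)
    ind <- ind & (if (m$sign[i] == "+") x > q else x <= q)
  }
  out <- as.integer(ind)
  attr(out, "prevalence") <- mean(out)
  out
}

#' Shift every threshold of a clique by a fixed number of percentiles
#'
#' Used by the sensitivity analysis that re-runs the downstream associations
#' with all thresholds moved up or down (typically by ten percentiles) to
#' check that the directionality of the estimates is preserved.
#'
#' @param clique a `thresholded_clique`.
#' @param delta percentile shift (may be negative).
#' @return the shifted `thresholded_clique`.
#' @export
perturb_thresholds <- function(clique, delta) {
  stopifnot(inherits(clique, "thresholded_clique"), is.numeric(delta),
            length(delta) == 1)
  p <- clique$members$percentile + delta
  if (any(p <= 0) || any(p >= 100)) {
    mc_user_error(
      "perturbed percentile(s) leave (0, 100): %s",
      paste(format(p[p <= 0 | p >= 100]), collapse = ", "))
  }
  thresholded_clique(clique$members$exposure, clique$members$sign, p)
}

#' JSON-ready list form of a clique (round-trips with [clique_from_list()])
#' @param clique a `thresholded_clique`.
#' @export
clique_to_list <- function(clique) {
  stopifnot(inherits(clique, "thresholded_clique"))
  list(members = clique$members)
}

#' @rdname clique_to_list
#' @param x a list as produced by [clique_to_list()] (e.g. read from JSON).
#' @export
clique_from_list <- function(x) {
  m <- as.data.frame(x$members, stringsAsFactors = FALSE)
  thresholded_clique(m$exposure, m$sign, m$percentile)
}
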