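# Reading, writing and validating cohort tables.

#' Names of the analysis covariates
#' @return character vector.
#' @export
covariate_names <- function() {
  c("sex", "ses", "maternal_age", "maternal_bmi", "child_age", "batch")
}

#' Coerce a data frame to a validated cohort table
#'
#' Checks the schema invariants: exposure columns numeric and strictly
#' positive where observed, `tcdi` within \[0, 100\] (it is a normalized
#' t-score), binary flags coded 0/1, and `ses` a three-level factor.
#' `log_tcdi` (natural log) is derived if absent.
#'
#' @param df a data frame.
#' @param exposures exposure column names expected; defaults to the 11-metal,
#'   2-trimester grid.
#' @return a `cohort_table`.
#' @export
as_cohort_table <- function(df, exposures = exposure_keys()) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(
    c("participant_id", exposures, "microbe_present", "tcdi",
      covariate_names()),
    names(df))
  if (length(missing_cols)) {
    mc_user_error("cohort table is missing column(s): %s",
                  paste(missing_cols, collapse = ", "))
  }
  for (e in exposures) {
    if (!is.numeric(df[[e]])) {
      mc_user_error("exposure column '%s' is not numeric", e)
    }
    if (any(df[[e]] <= 0, na.rm = TRUE)) {
      mc_user_error("exposure column '%s' has non-positive concentrations", e)
    }
  }
  if (any(df$tcdi < 0 | df$tcdi > 100, na.rm = TRUE)) {
    mc_user_error("tcdi outside [0, 100]")
  }
  for (b in c("microbe_present", "batch")) {
    if (!is_binary01(df[[b]])) mc_user_error("column '%s' must be 0/1", b)
  }
  if (!is.factor(df$ses)) {
    df$ses <- factor(df$ses, levels = c("lower", "medium", "higher"))
  }
  if (anyNA(df$ses)) mc_user_error("ses has unrecognized levels")
  if (is.null(df$log_tcdi)) df$log_tcdi <- log(df$tcdi)
  attr(df, "exposures") <- exposures
  class(df) <- unique(c("cohort_table", class(df)))
  df
}

#' Exposure column names of a cohort table
#' @param table a `cohort_table`.
#' @export
exposures_of <- function(table) {
  attr(table, "exposures") %||% exposure_keys()
}

#' Read a cohort table from CSV/TSV
#'
#' Rows with a missing outcome are dropped with a message stating the count
#' (a cohort of 123 stool-sampled children with 11 missing outcomes yields
#' the 112-row analysis table).
#'
#' @param path file path; comma-separated if it ends in `.csv`, otherwise
#'   tab-separated.
#' @param schema optional column mapping: a named character vector
#'   `canonical = file_column`, or a path to a YAML file with such a mapping.
#' @param exposures expected exposure columns.
#' @return a `cohort_table`.
#' @export
read_cohort <- function(path, schema = NULL, exposures = exposure_keys()) {
  if (!file.exists(path)) mc_user_error("file not found: %s", path)
  df <- if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    read.csv(path, stringsAsFactors = FALSE)
  } else {
    read.delim(path, stringsAsFactors = FALSE)
  }
  if (!is.null(schema)) {
    if (is.character(schema) && length(schema) == 1 && file.exists(schema)) {
      schema <- unlist(yaml::read_yaml(schema))
    }
    hit <- match(schema, names(df))
    if (anyNA(hit)) {
      mc_user_error("schema maps to absent column(s): %s",
                    paste(schema[is.na(hit)], collapse = ", "))
    }
    names(df)[hit] <- names(schema)
  }
  if (!"tcdi" %in% names(df)) mc_user_error("cohort table is missing column(s): tcdi")
  n_drop <- sum(is.na(df$tcdi))
  if (n_drop > 0) {
    message(sprintf("read_cohort: dropped %d row(s) with missing outcome (%d -> %d)",
                    n_drop, nrow(df), nrow(df) - n_drop))
    df <- df[!is.na(df$tcdi), , drop = FALSE]
    rownames(df) <- NULL
  }
  as_cohort_table(df, exposures = exposures)
}

#' Write a cohort table as TSV with a JSON metadata sidecar
#'
#' The sidecar `<path>.meta.json` records the generator seed (when known),
#' row count and column names, so a written cohort is self-describing.
#'
#' @param table a `cohort_table`.
#' @param path output TSV path.
#' @param seed optional integer recorded in the sidecar; defaults to the
#'   `synth_seed` attribute if present.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(table, path, seed = NULL) {
  stopifnot(inherits(table, "cohort_table"))
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(
    n = nrow(table),
    columns = names(table),
    seed = seed %||% attr(table, "synth_seed")
  )
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
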