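# Internal helpers shared across modules.

#' Signal a user-facing error
#'
#' Errors of class `mc_user_error` map to exit code 1 in the command-line
#' wrapper; anything else is an internal error (exit code 2).
#' @noRd
mc_user_error <- function(msg, ...) {
  stop(structure(
    class = c("mc_user_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sample quantile, linear-interpolation convention
#'
#' All percentile thresholds in the package use type-7 (linear interpolation)
#' sample quantiles; the subgroup semantics depend on this convention, so it
#' is fixed here rather than left to callers.
#' @noRd
mc_quantile <- function(x, prob) {
  stats::quantile(x, prob, type = 7, names = FALSE, na.rm = FALSE)
}

#' Derive a per-stage seed from a global seed
#'
#' Deterministic counter scheme: `stage_seed = (seed * 1009 + counter) mod
#' (2^31 - 1)`, so each pipeline stage is independently reproducible from the
#' single global seed.
#' @param seed integer global seed.
#' @param counter non-negative integer stage counter.
#' @return an integer seed below 2^31.
#' @export
fan_out_seed <- function(seed, counter) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.numeric(counter))
  as.integer((abs(seed) * 1009 + counter) %% 2147483647)
}

#' Run an expression with a local RNG state
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' @noRd
is_binary01 <- function(x) all(x %in% c(0, 1, NA))

#' @noRd
assert_scalar_prob <- function(x, name, open = TRUE) {
  ok <- is.numeric(x) && length(x) == 1 && !is.na(x) &&
    (if (open) x > 0 && x < 1 else x >= 0 && x <= 1)
  if (!ok) {
    mc_user_error("`%s` must be a single probability %s, got %s",
                  name, if (open) "in (0,1)" else "in [0,1]",
                  paste(format(x), collapse = ","))
  }
  invisible(x)
}
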