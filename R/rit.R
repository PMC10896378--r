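# Random intersection trees (RIT).
#
# Given a collection of weighted feature-sets (here: signed leaf sets from a
# forest), each RIT draws sets with probability proportional to weight down
# a tree of fixed depth and branching factor, intersecting along every
# root-to-leaf path.  Sets of features that co-occur in many input sets
# survive the repeated intersections; rare combinations die out
# geometrically.  Surviving intersections of sufficient order are the
# candidate clique signatures.

#' RIT hyperparameters
#' @param depth number of levels per intersection tree (root = level 1).
#' @param n_children branching factor.
#' @param n_trees number of intersection trees.
#' @param min_order minimum signature order retained (>= 2: an interaction).
#' @return a list of class `rit_params`.
#' @export
rit_params <- function(depth = 3, n_children = 2, n_trees = 20,
                       min_order = 2) {
  structure(list(depth = depth, n_children = n_children, n_trees = n_trees,
                 min_order = min_order), class = "rit_params")
}

#' Run random intersection trees over weighted signed sets
#'
#' @param sets list of character vectors (signed features).
#' @param weights sampling weights, one per set; default uniform.
#' @param params a [rit_params()].
#' @param seed integer seed.
#' @return character vector of canonical signature strings (members sorted,
#'   joined by `" & "`), deduplicated, each of order >= `min_order`.
#' @export
random_intersection_trees <- function(sets, weights = NULL,
                                      params = rit_params(), seed = 1L) {
  if (length(sets) == 0 || all(lengths(sets) == 0)) {
    mc_user_error("need at least one nonempty set")
  }
  if (params$depth < 1) mc_user_error("depth must be >= 1")
  if (params$n_children < 1) mc_user_error("n_children must be >= 1")
  if (is.null(weights)) weights <- rep(1, length(sets))
  stopifnot(length(weights) == length(sets), all(weights >= 0),
            sum(weights) > 0)
  with_seed(seed, {
    found <- character(0)
    for (tr in seq_len(params$n_trees)) {
      level <- list(sets[[sample.int(length(sets), 1, prob = weights)]])
      if (params$depth > 1) {
        for (d in seq_len(params$depth - 1)) {
          nxt <- vector("list", length(level) * params$n_children)
          j <- 0
          for (parent in level) {
            for (ch in seq_len(params$n_children)) {
              j <- j + 1
              if (length(parent) == 0) { nxt[[j]] <- parent; next }
              draw <- sets[[sample.int(length(sets), 1, prob = weights)]]
              nxt[[j]] <- parent[parent %in% draw]
            }
          }
          level <- nxt
        }
      }
      keep <- level[lengths(level) >= params$min_order]
      if (length(keep)) {
        found <- c(found, vapply(keep, function(s) {
          paste(sort(s, method = "radix"), collapse = " & ")
        }, ""))
      }
    }
    unique(found)
  })
}
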