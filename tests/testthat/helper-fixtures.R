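# Shared fixtures and independent oracles, all built in code.

# a small planted-effect cohort; defaults keep unit tests fast
small_cohort <- function(n = 120, seed = 1, ...) {
  generate_cohort(synth_config(n_participants = n, seed = seed, ...))
}

# independent exposures (diagonal copula) make prevalence arithmetic exact
indep_config <- function(n = 112, seed = 1, ...) {
  synth_config(n_participants = n, seed = seed, exposure_rho = 0, ...)
}

# brute-force Benjamini-Hochberg: min over j >= i (by sorted rank) of p(j)*n/j
bh_brute <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o]
  adj <- sapply(seq_len(n), function(i) {
    min(1, min(ranked[i:n] * n / seq(i, n)))
  })
  out <- numeric(n)
  out[o] <- adj
  out
}

# exhaustive two-sided Fisher p for a 2x2 table with fixed margins
fisher2x2_brute <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); N <- sum(tab)
  ks <- max(0, c1 - (N - r1)):min(r1, c1)
  probs <- stats::dhyper(ks, r1, N - r1, c1)
  p_obs <- stats::dhyper(tab[1, 1], r1, N - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exhaustive RIT survival probability: probability that `target` survives a
# single intersection tree of given depth/branching over weighted sets
rit_exact_prob <- function(sets, weights, target, depth, n_children) {
  pr <- weights / sum(weights)
  contains <- vapply(sets, function(s) all(target %in% s), TRUE)
  p <- sum(pr[contains])     # prob a single draw contains the target
  # target survives at a leaf iff every draw on the root-to-leaf path
  # contains it; leaves share the root draw, so survival anywhere in the
  # tree: P(root has it) * P(at least one leaf path of extra draws has it).
  # depth d path = root + (d-1) further draws; with full branching the
  # subtree below the root has n_children^(d-1) leaves but draws are shared
  # along paths.  Computed by recursion on subtree survival.
  subtree <- function(levels_left) {
    if (levels_left == 0) return(1)      # survived to a leaf
    # child survives if its draw contains target and its subtree does
    p_child <- p * subtree(levels_left - 1)
    1 - (1 - p_child)^n_children
  }
  p * subtree(depth - 1)
}

# all permutations of seq_len(n) (n small), for exhaustive permutation tests
all_perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}
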