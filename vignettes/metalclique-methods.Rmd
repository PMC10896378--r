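---
title: "Discovering signed metal-cliques and microbiome effect modification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering signed metal-cliques and microbiome effect modification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metalclique)
```

## The scientific problem

Prenatal exposure to metals rarely acts one element at a time. A
*metal-clique* is a small, signed, thresholded combination of exposures —
for example, "zinc above its 20th sample percentile in the second
trimester, cobalt at or below its 80th percentile in the third, chromium at
or below its 55th in the second" — that defines a binary subgroup of
children. The hypothesis behind this package is that such subgroups can
carry associations with a continuous child outcome (here, a log-transformed
t-scored depression inventory) that no single metal shows, and that the
association can be modified by the presence of a beneficial gut microbe
measured in childhood stool.

The pipeline has three stages:

1. **Screening.** Covariate-adjusted linear models of the log outcome on
   each exposure (22 of them: 11 metals in 2 trimesters), with
   Benjamini–Hochberg FDR across the exposure family, and on the microbe
   presence flag.
2. **Discovery.** The repeated-holdout signed iterated random forest
   (rh-SiRF) searches for signed exposure combinations that sit on
   predictive decision paths, and ranks them by *stability*: the fraction
   of repeated train/test splits in which the combination re-appears.
   The top combinations are then turned into a single binary indicator by
   an exhaustive quantile-grid threshold search.
3. **Inference.** The indicator's association with the outcome is estimated
   by weighted least squares on a covariate-balanced sample
   (propensity-score subclassification), stratified by microbe presence,
   with randomization p-values from outcome permutation and a suite of
   sensitivity analyses (threshold perturbation, outcome binarization, a
   negative-control outcome, an unweighted re-fit).

## The rh-SiRF engine

Within one holdout the cohort is split 60/40. On the training half an
*iterated* regression forest is grown: iteration 1 samples split candidates
uniformly; iteration *k+1* samples them with probability proportional to
iteration *k*'s impurity importances, so features that carry signal —
marginally or conditionally — are progressively enriched on decision
paths. The final forest must predict the held-out 40% (test R² above a
configurable floor, default 0) for the holdout to count at all: discovered
combinations are required to be predictive out of sample, not merely
fitted.

The training half is then bootstrapped. Each bootstrap regrows a small
forest under the final feature weights, each leaf contributes the *signed
set* of features on its root-to-leaf path ("+" for the `>` branch, "−" for
the `≤` branch; the deepest sign wins if a feature recurs), weighted by the
number of bootstrap observations in the leaf. Random intersection trees
(RIT) then intersect randomly drawn leaf sets: combinations that co-occur
on many paths survive; incidental ones die out geometrically. A signature
counts for the holdout when it appears in at least a fraction (default
10%) of bootstraps; stability is the fraction of holdouts retaining it.

Two design choices deserve emphasis, both genuinely open in the original
method description:

* **Two forest parameter sets.** The iteration-stage forest runs only a few
  times per holdout but its importances steer everything downstream, so it
  defaults to more trees (150) and a wide `mtry` (15) for a low-variance,
  greedy importance estimate. The per-bootstrap forests are many (250 per
  holdout at full scale) and can be small (100 trees at full scale, far
  fewer in reduced configurations); their job is only to convert the final
  weights into signed co-occurrence paths.
* **Permissive RITs, strict support.** RITs default to depth 2 (one
  intersection per path) with 40 trees; the within-holdout bootstrap
  support threshold, not the intersection depth, does the denoising.

The bootstrap-counting rule and the predictivity filter are explicit knobs
(`bootstrap_support`, `predictivity_floor`); the original publications do
not pin them down, and we make no claim that these defaults reproduce the
original implementation.

## Threshold finding

A discovered signature fixes which exposures and which sides; the
threshold search fixes where. For every combination of percentiles on a
grid (default 5–95 by 5, covering the published 20/80/55 pattern), the
induced indicator is regressed (with covariates) on the outcome, and the
candidate maximizing |t| wins, subject to prevalence bounds (default
0.05–0.95) that preclude degenerate subgroups at n ≈ 112. The |t|
objective is the main methodological free parameter: the method
description says only that the binarized clique is "used in a regression
framework", so the package optimizes association strength and documents
it. Ties break toward the median (50th percentile), then lexicographically,
making the search fully deterministic. All quantiles throughout the package
are type-7 (linear interpolation) sample quantiles; the boundary convention
is strict `>` for "+" members and `≤` for "−" members.

Because the indicator depends on exposures only through ranks, it is
invariant to any strictly monotone transform of each exposure — a property
the test suite asserts directly.

## Covariate balancing and inference

Microbe presence is not randomized; children with and without the microbe
differ in measured covariates (child sex, 3-level SES, maternal age and
BMI, child age at stool collection, sequencing batch). The package
estimates a logistic propensity score on all covariates, cuts it into
subclasses at propensity quantiles (default 6; subclasses missing a group
are merged toward the median), and assigns marginal-mean-weighting-through-
stratification weights `(n_s/N)·(N_g/n_{s,g})`, which preserve each group's
total size. Standardized mean differences — weighted mean difference over
the *unweighted* full-sample pooled SD, so before/after share one scale —
are the love-plot diagnostic.

Stratified estimates (separate weighted fits within microbe-absent and
microbe-present children) are the headline output, with stratum
prevalences reported against the full sample so they sum to the overall
clique prevalence; a product-term model supplies the formal interaction
test. Randomization p-values permute the outcome vector only, keeping the
design and weights fixed, and use the add-one correction
`(1 + #{|t*| ≥ |t|})/(1 + B)`; the full-scale analysis uses B = 10⁶,
while tests and default runs use 10⁴. Note an intentional asymmetry the
suite documents: for a *pre-specified* clique the permutation p is uniform
under the null, but the p-value of a clique *returned by the threshold
search* is stochastically smaller than uniform — the selection effect that
the split-sample discovery stage exists to contain.

## The synthetic cohort

Every stage is testable without cohort data through a generator that
emulates the study conditions: n = 112; 11 metals × 2 trimesters as
correlated log-normals (Gaussian copula on the log scale; exchangeable
ρ = 0.2 by default, since only "minimal" inter-metal correlation is
reported and no matrix is published); blood-metal geometric means set to
typical maternal values (e.g. Zn ≈ 4800 µg/L, Pb ≈ 35 µg/L) with tighter
log-SDs for homeostatically regulated elements (Zn, Se, Cu); microbe
prevalence 24% with a covariate-linked log-odds (intercept calibrated so
the expected prevalence is exact); outcome log-normal with t-score mean 53
and SD 8.1; sex 60.7% male; SES ≈ 0.55/0.37/0.09; MCAR missingness under
5% confined to maternal age and child age; and an independent
Bernoulli(0.5) pet-ownership flag as negative control. A planted
thresholded clique (default: the Zn⁺/Co⁻/Cr⁻ pattern at 20/80/55) adds
`effect_in_absent`·I(clique)·I(no microbe) +
`effect_in_present`·I(clique)·I(microbe) on the log-outcome scale, centered
so the marginal outcome calibration is preserved; the defaults (+0.11 /
−0.05) mirror the magnitude of stratified estimates reported for the real
cohort.

What the generator does *not* emulate: real inter-metal correlation
structure (block patterns by trimester, nutrient–toxicant relationships),
measurement error and detection limits, informative missingness, or any
link between exposures and microbe colonization. Passing tests therefore
demonstrate the machinery's correctness and calibration under the stated
statistical structure, not performance on real exposomic data.

## Problem sizes, power, and a documented limitation

Unit tests run the engine at deliberately small configurations (a handful
of holdouts and bootstraps) to exercise mechanics. The property studies
use a reduced discovery configuration — 100 holdouts × 50 bootstraps,
15-tree bootstrap forests, 100-tree iteration forests — and 20 replicate
cohorts of n = 300 with the planted effect at half the residual log-scale
SD (≈ 0.076).

At that signal size the discovery problem is near the information
boundary, and this is worth stating precisely. The planted effect is
carried by a three-way conjunction, so each member's *marginal*
correlation with the outcome is only ≈ 0.05–0.15, while the maximum
spurious correlation among the 19 noise exposures in a draw of n = 300 is
typically ≈ 0.10–0.17: in only about a fifth of draws do two of the three
true members rank in the top 3 by marginal association, and even an oracle
that conditions on the correct member at the correct threshold lifts a
second member into the conditional top 3 in only about two-thirds of
draws. Consistently placing a true 2-subset in the top 3 stability records
in ≥ 80% of such draws is therefore beyond what the data support; in our
measurements the engine achieves roughly a quarter to a third. When the
planted effect is 1.0 SD the same engine and configuration place a true
subset at rank 1–2 essentially always, which localizes the limitation in
the signal-to-noise ratio rather than the implementation. The
corresponding acceptance test asserts the stricter property and is
expected to fail at the half-SD setting; it is retained unchanged as
documentation of that boundary.

## Numerical and degenerate-input conventions

* Natural log throughout (`log_tcdi = log(tcdi)`, defined only for
  `tcdi > 0`; scores are clamped to the instrument's \[0, 100\] scale).
* PMM imputation: chained equations with 5 sweeps, 5 donors, one completed
  dataset carried forward (no Rubin pooling — the downstream discovery
  needs a single rectangle); imputed values always belong to the observed
  support of the column; fully deterministic given a seed.
* Two-sided Fisher p-values sum the probabilities of tables at most as
  probable as the observed one; Wilcoxon tests follow the exact /
  normal-approximation switching of `stats::wilcox.test`. Spearman is the
  default exposure correlation (the methods text mentions Pearson once;
  both are available and the discrepancy is surfaced here rather than
  resolved).
* Constant columns yield `NA` correlations with a warning; zero pooled SDs
  yield SMD 0 with a flag; degenerate clique indicators, empty strata, and
  logistic separation raise or flag explicitly rather than silently
  propagating.
* Row-order invariance of the discovery stage is obtained by canonically
  ordering rows by participant id before any random split.
* A single global seed fans out to stage seeds via
  `fan_out_seed(seed, counter) = (1009·seed + counter) mod (2³¹ − 1)`.
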