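# metalclique

Signed metal-clique discovery and microbiome effect modification for
environmental mixture analysis.

## What it does

Epidemiologic mixtures questions are usually asked one exposure at a time,
or as a single weighted index of all exposures. This package implements a
middle path: it searches for **metal-cliques** — small, signed, thresholded
combinations of prenatal blood-metal concentrations, such as

```
Zn_T2+@20 & Co_T3-@80 & Cr_T2-@55
```

("zinc above its 20th sample percentile in trimester 2, cobalt at or below
its 80th percentile in trimester 3, chromium at or below its 55th in
trimester 2") — that define a binary subgroup of children whose
log-transformed, t-scored depression inventory (log-tCDI) differs from the
rest, and it tests whether that association is **modified by the presence
of a gut microbe** in childhood stool.

The discovery engine is a repeated-holdout signed iterated random forest
(**rh-SiRF**): per train/test split, an importance-reweighted regression
forest is grown on the training 60%; signed root-to-leaf path sets
("+" = high side of a split, "−" = low side) weighted by leaf occupancy are
mined with **random intersection trees**; and a combination's **stability**
is the fraction of 500 holdouts (250 bootstraps each, at full scale) in
which it re-appears, provided the forest predicts the held-out 40%. A
quantile-grid search then binarizes the winning signature by maximizing the
covariate-adjusted |t| of its indicator, and inference proceeds on a
covariate-balanced sample (propensity-score subclassification with
stratification weights), with stratified effect-modification estimates,
randomization p-values (outcome permutation), and sensitivity analyses:
±10-percentile threshold perturbation, outcome binarization at the 75th
percentile, an unweighted re-fit, and a negative-control outcome (pet
ownership).

A synthetic-cohort generator with a plantable clique-by-microbe interaction
(n = 112, 24% microbe prevalence, t-score mean 53 / SD 8.1, weakly
correlated log-normal metals) makes the whole pipeline runnable and
testable without any data download.

## Worked example

```r
library(metalclique)

cfg    <- synth_config(n_participants = 112, seed = 1)   # planted defaults
cohort <- pmm_impute(generate_cohort(cfg), seed = 2)

bal <- balance_cohort(cohort)                 # propensity subclassification
em  <- effect_modification(cohort, cfg$planted_clique, weights = bal$weight,
                           n_permutations = 10000, seed = 3)
em
```

```
Overall: Co_T3-@80 & Cr_T2-@55 & Zn_T2+@20: beta = 0.06494 [0.0003596, 0.1295], p = 0.0488, n = 112
Absent : Co_T3-@80 & Cr_T2-@55 & Zn_T2+@20 | microbe absent: beta = 0.08628 [0.01198, 0.1606], p = 0.0235, n = 81
Present: Co_T3-@80 & Cr_T2-@55 & Zn_T2+@20 | microbe present: beta = -0.05689 [-0.1946, 0.08078], p = 0.401, n = 31
```

The generator planted a log-scale effect of +0.11 in microbe-absent
children and −0.05 in microbe-present children; at n = 112 a single draw
recovers the pattern — positive and significant where the microbe is
absent, negative and null where it is present — with the expected
single-draw noise in the magnitudes. `run_pipeline()` chains the full
sequence (simulate → impute → describe → screen → discover → binarize →
balance → infer → sensitivity) and writes TSV/JSON artifacts; the same
stages are available from a shell via `inst/cli/metalclique.R
<subcommand> --seed N --out DIR`.

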