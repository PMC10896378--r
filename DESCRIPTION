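Package: metalclique
Title: Signed Metal-Clique Discovery and Microbiome Effect Modification
    in Environmental Mixture Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovers signed, thresholded combinations of prenatal metal
    exposures ("metal-cliques") associated with a continuous child outcome,
    using a repeated-holdout signed iterated random forest (rh-SiRF):
    importance-reweighted regression forests, signed decision-path
    extraction, random intersection trees, and stability estimation over
    repeated train/test splits.  A quantile-based threshold search turns a
    discovered signature into a binary subgroup indicator, whose association
    with the outcome is estimated on a covariate-balanced sample
    (propensity-score subclassification) with randomization-based p-values,
    stratified effect-modification estimates by gut-microbe presence, and a
    battery of sensitivity analyses including a negative-control outcome.
    A synthetic-cohort generator with a plantable clique-by-microbe
    interaction makes every stage testable without access to cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ranger,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
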