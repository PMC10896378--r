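# End-to-end pipeline orchestration and the command-line entry point.
#
# The pipeline chains the three analysis stages (single-exposure screen;
# microbe association; clique discovery -> binarization -> balanced
# inference -> sensitivity suite) over TSV/JSON artifacts in an output
# directory, so each stage can also be re-run independently from the
# artifacts of the previous ones.  A single global seed fans out to
# per-stage seeds through fan_out_seed(seed, stage_counter).

#' Pipeline configuration
#'
#' Defaults reflect the full-scale analysis (500 holdouts, 250 bootstraps,
#' 1e6-permutation p-values are *not* defaulted here: permutations default
#' to 1e4 to keep desk runs tractable; raise `n_permutations` for final
#' runs).  Unknown keys in `overrides` are rejected.
#'
#' @param overrides named list of settings to override; nested lists merge
#'   by key (e.g. `list(sirf = list(n_holdouts = 50))`).
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(overrides = list()) {
  defaults <- list(
    input = NULL,              # path to a cohort TSV/CSV; NULL = simulate
    schema = NULL,             # optional column-mapping YAML for `input`
    out_dir = "metalclique_out",
    seed = 1L,
    synth = list(n_participants = 112),
    impute = list(n_iterations = 5, k_donors = 5),
    sirf = list(n_holdouts = 500, train_fraction = 0.6, n_bootstraps = 250,
                n_iterations = 3, num_trees = 100, max_depth = 3,
                min_node_size = 20, mtry = 15, iter_num_trees = 150,
                iter_max_depth = 4, iter_min_node_size = 20, iter_mtry = 15,
                rit_depth = 2, rit_children = 2, rit_trees = 40,
                predictivity_floor = 0, bootstrap_support = 0.1,
                max_order = 3),
    binarize = list(grid_step = 5, prevalence_lo = 0.05, prevalence_hi = 0.95,
                    top_k = 3),
    balance = list(n_subclasses = 6),
    inference = list(n_permutations = 10000),
    sensitivity = list(items = 1:6, n_permutations = 10000,
                       perturb_delta = 10, binarize_percentile = 75),
    verbose = TRUE
  )
  cfg <- merge_config(defaults, overrides, path = "")
  structure(cfg, class = "pipeline_config")
}

#' @noRd
merge_config <- function(defaults, overrides, path) {
  if (length(overrides) == 0) return(defaults)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    mc_user_error("unknown config key(s): %s",
                  paste0(path, unknown, collapse = ", "))
  }
  for (k in names(overrides)) {
    if (is.list(defaults[[k]]) && is.list(overrides[[k]]) &&
        !is.null(names(defaults[[k]]))) {
      defaults[[k]] <- merge_config(defaults[[k]], overrides[[k]],
                                    paste0(path, k, "."))
    } else {
      defaults[k] <- overrides[k]
    }
  }
  defaults
}

#' Read a pipeline configuration from YAML (or JSON)
#' @param path file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) mc_user_error("config file not found: %s", path)
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  pipeline_config(raw %||% list())
}

#' @noRd
sirf_config_from <- function(cfg) {
  s <- cfg$sirf
  sirf_config(
    n_holdouts = s$n_holdouts, train_fraction = s$train_fraction,
    n_bootstraps = s$n_bootstraps, n_iterations = s$n_iterations,
    forest = forest_params(num_trees = s$num_trees, max_depth = s$max_depth,
                           min_node_size = s$min_node_size, mtry = s$mtry),
    iteration_forest = forest_params(num_trees = s$iter_num_trees,
                                     max_depth = s$iter_max_depth,
                                     min_node_size = s$iter_min_node_size,
                                     mtry = s$iter_mtry),
    rit = rit_params(depth = s$rit_depth, n_children = s$rit_children,
                     n_trees = s$rit_trees),
    predictivity_floor = s$predictivity_floor,
    bootstrap_support = s$bootstrap_support, max_order = s$max_order)
}

#' Choose the working signature from stability records
#'
#' Takes the top-k records; when their union network is a closed loop whose
#' nodes carry one sign per exposure, the union of nodes is the working
#' signature (this is how three stable two-component combinations yield one
#' three-component clique).  Otherwise the single top signature is used.
#'
#' @param records a `stability_records` data frame.
#' @param k how many top records to consider.
#' @return character vector of signed features, with attribute
#'   `from_closed_loop`.
#' @export
select_signature <- function(records, k = 3) {
  if (nrow(records) == 0) mc_user_error("no stability records to select from")
  top1 <- strsplit(records$signature[1], " & ", fixed = TRUE)[[1]]
  if (nrow(records) < 2 || k < 2) {
    return(structure(top1, from_closed_loop = FALSE))
  }
  net <- clique_network(records, k = min(k, nrow(records)))
  if (net$closed_loop) {
    expo <- sub("[+-]$", "", net$nodes)
    if (!anyDuplicated(expo)) {
      return(structure(net$nodes, from_closed_loop = TRUE))
    }
  }
  structure(top1, from_closed_loop = FALSE)
}

#' Run the full pipeline
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a list of in-memory results; artifacts are written
#'   under `config$out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (isTRUE(config$verbose)) message(sprintf(...))
  seed <- config$seed

  # stage 1: obtain the cohort
  if (is.null(config$input)) {
    say("simulate: n = %d (seed %d)", config$synth$n_participants, seed)
    sc <- do.call(synth_config,
                  c(config$synth, list(seed = fan_out_seed(seed, 1))))
    cohort <- generate_cohort(sc)
    write_cohort(cohort, file.path(out, "cohort.tsv"))
  } else {
    cohort <- read_cohort(config$input, schema = config$schema)
  }

  # stage 2: imputation
  cohort <- pmm_impute(cohort, n_iterations = config$impute$n_iterations,
                       k_donors = config$impute$k_donors,
                       seed = fan_out_seed(seed, 2))
  write_cohort(cohort, file.path(out, "cohort_imputed.tsv"))

  # stage 3: descriptives and correlations
  desc <- descriptives(cohort)
  write.table(desc, file.path(out, "descriptives.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cm <- correlation_matrix(cohort)
  write.table(round(cm, 4), file.path(out, "correlation.tsv"), sep = "\t",
              quote = FALSE, col.names = NA)

  # stage 4: single-exposure screen
  scr <- screen_all(cohort)
  write.table(scr, file.path(out, "screen.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  # stage 5: clique discovery
  say("discover: %d holdouts x %d bootstraps",
      config$sirf$n_holdouts, config$sirf$n_bootstraps)
  records <- rh_sirf(cohort, sirf_config_from(config),
                     seed = fan_out_seed(seed, 5))
  write.table(records, file.path(out, "stability.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  net <- if (nrow(records) >= 2) clique_network(records, config$binarize$top_k)
         else NULL
  if (!is.null(net)) {
    write.table(net$edges, file.path(out, "network_edges.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  # stage 6: binarize the selected signature
  signature <- select_signature(records, config$binarize$top_k)
  say("binarize: %s", paste(signature, collapse = " & "))
  clique <- find_thresholds(
    signature, cohort,
    grid = seq(config$binarize$grid_step, 100 - config$binarize$grid_step,
               by = config$binarize$grid_step),
    prevalence_bounds = c(config$binarize$prevalence_lo,
                          config$binarize$prevalence_hi))
  jsonlite::write_json(
    c(clique_to_list(clique),
      list(string = format(clique), from_closed_loop =
             isTRUE(attr(signature, "from_closed_loop")))),
    file.path(out, "clique.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)

  # stage 7: covariate balancing
  bal <- balance_cohort(cohort, n_subclasses = config$balance$n_subclasses)
  write.table(love_table(bal), file.path(out, "love.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(
    data.frame(participant_id = cohort$participant_id,
               propensity = bal$propensity, subclass = bal$subclass,
               weight = bal$weight),
    file.path(out, "weights.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)

  # stage 8: balanced inference with effect modification
  em <- effect_modification(cohort, clique, weights = bal$weight,
                            n_permutations = config$inference$n_permutations,
                            seed = fan_out_seed(seed, 8))
  jsonlite::write_json(
    list(overall = unclass(em$overall),
         stratum_absent = if (!is.null(em$stratum_absent)) unclass(em$stratum_absent),
         stratum_present = if (!is.null(em$stratum_present)) unclass(em$stratum_present),
         prevalence_absent = em$prevalence_absent,
         prevalence_present = em$prevalence_present,
         inestimable = em$inestimable),
    file.path(out, "association.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA, force = TRUE)

  # stage 9: sensitivity suite
  sens <- run_sensitivity_suite(
    cohort, clique, weights = bal$weight,
    config = sensitivity_config(
      items = config$sensitivity$items,
      n_permutations = config$sensitivity$n_permutations,
      perturb_delta = config$sensitivity$perturb_delta,
      binarize_percentile = config$sensitivity$binarize_percentile,
      seed = fan_out_seed(seed, 9)))
  write_sensitivity_report(sens, out)

  invisible(list(cohort = cohort, descriptives = desc, screen = scr,
                 records = records, network = net, clique = clique,
                 balance = bal, effect_modification = em,
                 sensitivity = sens))
}
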