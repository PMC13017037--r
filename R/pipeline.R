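#' Configuration of a full pipeline run
#'
#' Collects every stage parameter with its default: the input source (a
#' [cohort_config()] for synthetic data, or a directory of raw tables),
#' the trial-aggregation switches, the network node set and estimator, and
#' all simulation / imputation / bootstrap sizes. Per-stage seeds are
#' derived deterministically from the master seed.
#'
#' @param cohort A [cohort_config()], or a directory path for
#'   [read_cohort()].
#' @param trials,stress,flexibility Aggregation switches, see
#'   [build_trait_table()]; `control = TRUE` is shorthand for the control
#'   preset (first-trial lateralization and behavior, raw stress bpm, raw
#'   reversal days).
#' @param control Logical; apply the control preset.
#' @param node_set `"12"` (default; absolute lateralization only) or
#'   `"14"` (adds the relative indices).
#' @param estimator Network estimator, `"ebicglasso"` or `"cor"`.
#' @param n_replicates Chance-simulation replicates (default 10000).
#' @param m,maxit,donors Imputation settings (defaults 5 / 50 / 5).
#' @param n_boot_edges Edge-bootstrap resamples (default 1000).
#' @param n_boot_cs Case-dropping subsets per proportion (default 1000).
#' @param seed Master seed.
#' @return A `run_config` list.
#' @export
run_config <- function(cohort = cohort_config(),
                       trials = c("mean", "first"),
                       stress = c("index", "raw"),
                       flexibility = c("index", "raw"),
                       control = FALSE,
                       node_set = c("12", "14"),
                       estimator = c("ebicglasso", "cor"),
                       n_replicates = 10000,
                       m = 5, maxit = 50, donors = 5,
                       n_boot_edges = 1000, n_boot_cs = 1000,
                       seed = 1L) {
  trials <- match.arg(trials)
  stress <- match.arg(stress)
  flexibility <- match.arg(flexibility)
  if (isTRUE(control)) {
    trials <- "first"
    stress <- "raw"
    flexibility <- "raw"
  }
  structure(
    list(
      cohort = cohort,
      trials = trials, stress = stress, flexibility = flexibility,
      control = isTRUE(control),
      node_set = match.arg(as.character(node_set), c("12", "14")),
      estimator = match.arg(estimator),
      n_replicates = n_replicates,
      m = m, maxit = maxit, donors = donors,
      n_boot_edges = n_boot_edges, n_boot_cs = n_boot_cs,
      seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

#' Run the full trait-covariation analysis
#'
#' Executes every stage in order — generate or ingest the raw cohort,
#' score the trait table, run the chance-performance simulation at the
#' observed day horizon, the univariate battery, multiple imputation (when
#' cells are missing), network estimation with edge bootstrap, centrality
#' and case-dropping stability — writing every intermediate artifact, a
#' consolidated JSON report and a log to `out_dir`. Re-running with the
#' same config reproduces all stochastic outputs exactly.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return The results, invisibly: a list with the cohort, trait table,
#'   null distribution, imputation set, networks and stability objects.
#' @export
run_pipeline <- function(config = run_config(), out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  log_line <- function(...) {
    cat(paste0(..., "\n"), file = log_path, append = TRUE)
  }
  cat("", file = log_path)
  log_line("traitnet pipeline, package version ",
    as.character(utils::packageVersion("traitnet")))
  log_line("master seed: ", config$seed)

  # -- input ---------------------------------------------------------------
  if (inherits(config$cohort, "cohort_config")) {
    cfg <- config$cohort
    cfg$seed <- derive_seed(config$seed, "cohort")
    cohort <- generate_cohort(cfg)
    log_line("generated synthetic cohort: ", cfg$n_subjects, " subjects")
  } else {
    cohort <- read_cohort(config$cohort)
    log_line("read cohort from ", config$cohort)
  }
  write_cohort(cohort, file.path(out_dir, "cohort"))

  # -- scoring -------------------------------------------------------------
  traits <- build_trait_table(
    cohort,
    trials = config$trials, stress = config$stress,
    flexibility = config$flexibility
  )
  write_trait_table(traits, file.path(out_dir, "trait_table.tsv"))
  n_missing <- sum(is.na(traits[trait_names()]))
  log_line("trait table: ", nrow(traits), " subjects, ", n_missing,
    " missing cells")

  # -- chance simulation at the observed day horizon -----------------------
  phases <- maze_phase_results(cohort)
  horizon <- max(phases$days_to_criterion, na.rm = TRUE)
  n_learning <- sum(phases$phase == "learning")
  null <- simulate_chance_experiment(
    n_subjects = n_learning, n_days = horizon,
    trials_per_day = attr(cohort, "config")$trials_per_day %||% 6,
    n_replicates = config$n_replicates,
    seed = derive_seed(config$seed, "chance")
  )
  observed <- sum(
    !is.na(phases$days_to_criterion[phases$phase == "learning"])
  )
  pv <- pvalue_observed(null, observed)
  readr::write_tsv(tidy(null), file.path(out_dir, "chance_null.tsv"))
  log_line(sprintf(
    "chance null (%d days): %.2f +/- %.2f%%; observed %d/%d, p %s",
    horizon, null$mean_percentage, null$sd_percentage, observed,
    n_learning, pv$label
  ))

  # -- univariate battery --------------------------------------------------
  battery <- univariate_battery(traits)
  readr::write_tsv(battery, file.path(out_dir, "univariate_battery.tsv"))

  # -- imputation ----------------------------------------------------------
  if (n_missing > 0) {
    imp <- pmm_impute(
      traits,
      m = config$m, maxit = config$maxit, donors = config$donors,
      seed = derive_seed(config$seed, "imputation")
    )
    write_imputation_set(imp, file.path(out_dir, "imputation"))
    net_input <- imp
    boot_table <- imp$completed_tables[[1]]
    log_line("imputed ", sum(imp$missing_mask), " cells (m = ", config$m,
      ")")
  } else {
    imp <- NULL
    net_input <- traits
    boot_table <- traits
  }

  # -- network -------------------------------------------------------------
  nodes <- network_nodes(config$node_set)
  select_nodes <- function(tab) tab[c("subject_id", nodes)]
  net_input_nodes <- if (inherits(net_input, "imputation_set")) {
    net_input$completed_tables <- lapply(
      net_input$completed_tables, select_nodes
    )
    net_input
  } else {
    select_nodes(net_input)
  }
  cm <- correlation_matrix(net_input_nodes)
  network <- estimate_network(cm,
    estimator = config$estimator, n = nrow(traits)
  )
  stability <- edge_bootstrap(
    select_nodes(boot_table),
    estimator = config$estimator,
    n_boot = config$n_boot_edges,
    seed = derive_seed(config$seed, "edges")
  )
  network$mask <- stability$network$mask
  cent <- centrality(network)
  cs <- cs_coefficient(
    select_nodes(boot_table),
    estimator = config$estimator,
    n_boot = config$n_boot_cs,
    seed = derive_seed(config$seed, "cs")
  )
  readr::write_tsv(tidy(cm), file.path(out_dir, "correlation_matrix.tsv"))
  readr::write_tsv(tidy(stability), file.path(out_dir, "edges.tsv"))
  readr::write_tsv(cent, file.path(out_dir, "centrality.tsv"))
  readr::write_tsv(tidy(cs), file.path(out_dir, "cs_detail.tsv"))
  log_line(
    "network: ", sum(network$weights[upper.tri(network$weights)] != 0),
    " edges, ", sum(stability$edges$significant), " significant"
  )

  # -- consolidated report -------------------------------------------------
  report <- list(
    seed = config$seed,
    settings = list(
      trials = config$trials, stress = config$stress,
      flexibility = config$flexibility, control = config$control,
      node_set = config$node_set, estimator = config$estimator
    ),
    n_subjects = nrow(traits),
    n_missing_cells = n_missing,
    chance_null = list(
      n_days = horizon, mean = null$mean_percentage,
      sd = null$sd_percentage, observed = observed, p_label = pv$label,
      p_value = pv$p_value
    ),
    network = list(
      nodes = network$nodes,
      n_edges = sum(network$weights[upper.tri(network$weights)] != 0),
      n_significant = sum(stability$edges$significant),
      lambda = network$lambda
    ),
    centrality = cent,
    cs = glance(cs)
  )
  jsonlite::write_json(
    report, file.path(out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(list(
    cohort = cohort, traits = traits, null = null, battery = battery,
    imputation = imp, correlation = cm, network = network,
    stability = stability, centrality = cent, cs = cs,
    report = report, out_dir = out_dir
  ))
}
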