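#' Read a pipeline run configuration
#'
#' The YAML config names the input tables (subjects, metabolites,
#' annotation, phenotype registry), the imputation and FDR settings, an
#' optional subgroup filter, the seed and the output directory. Missing
#' fields fall back to the documented defaults.
#'
#' @param path path to a YAML file.
#' @return A validated list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg a config list built in code instead of read from YAML.
#' @export
validate_run_config <- function(cfg) {
  defaults <- list(m = 5, n_iter = 10, donor_k = 5, seed = 1,
                   fdr_alpha = 0.05, models = c("Model1", "Model2"),
                   subgroup = NULL, out_dir = "atlas_out",
                   missingness_threshold = 0.75)
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  if (cfg$fdr_alpha <= 0 || cfg$fdr_alpha >= 1)
    stop("config field fdr_alpha must lie in (0, 1)")
  if (!all(cfg$models %in% c("Model1", "Model2")))
    stop("config field models must be a subset of Model1, Model2")
  if (!is.null(cfg$subgroup) &&
      !all(c("column", "value") %in% names(cfg$subgroup)))
    stop("config field subgroup needs 'column' and 'value'")
  structure(cfg, class = "run_config")
}

#' Simulate a cohort from a config and write its files
#'
#' Thin wrapper over [generate_cohort()] + [write_cohort()], writing a
#' manifest with the seed alongside the data.
#'
#' @param config a `run_config` (or list) with optional fields
#'   `n_subjects`, `n_metabolites`, `seed`, `effects`, `out_dir`.
#' @return Invisibly, the output directory.
#' @export
atlas_simulate <- function(config) {
  config <- validate_run_config(unclass(config))
  n <- if (is.null(config$n_subjects)) 500L else config$n_subjects
  n_met <- if (is.null(config$n_metabolites)) 40L else config$n_metabolites
  cc <- cohort_config(n, seed = config$seed)
  effects <- list()
  for (ef in config$effects) {
    effects <- c(effects, list(effect_spec(
      phenotype = ef$phenotype, metabolite = ef$metabolite,
      slope = ef$slope, amplitude = ef$amplitude,
      acrophase = if (is.null(ef$acrophase)) 0 else ef$acrophase)))
  }
  cohort <- generate_cohort(cc, default_phenotypes(),
                            default_metabolites(n_met), effects)
  paths <- write_cohort(cohort, config$out_dir)
  jsonlite::write_json(list(seed = config$seed, n_subjects = n,
                            n_metabolites = n_met,
                            files = as.list(paths)),
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(config$out_dir)
}

#' Imputation covariates used by the preprocessing stage
#'
#' The synthetic analogues of the metabolic-environment covariates: age,
#' sex, BMI plus the lifestyle variables. Passed explicitly so real-data
#' runs can substitute their own lab panel.
#' @return Character vector of column names.
#' @export
default_imputation_covariates <- function() {
  c("age", "sex", "bmi", "physical_activity", "diet_score")
}

#' Run the atlas pipeline end to end
#'
#' preprocess (filter, half-minimum, multiple imputation, rank
#' normalization, batch aggregation) -> association scan -> summaries
#' (counts, top-connected, Dice matrices) -> bipartite network (incidence,
#' metrics per superpathway, modularity, layout). Every stage appends its
#' counts to a log returned with (and written beside) the outputs.
#'
#' @param cohort a `sleep_cohort`, or a list with elements `subjects`,
#'   `metabolites`, `annotation`, `phenotypes` read from files.
#' @param config a `run_config` or plain list of settings.
#' @return List of class `atlas_run`: `results` (association table),
#'   `counts`, `top`, `dsc_domain`, `network` (incidence, metrics report,
#'   layout), `excluded`, `log`.
#' @export
atlas_run <- function(cohort, config = list()) {
  config <- validate_run_config(unclass(config))
  log <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    message("[sleepmwas] ", msg)
  }
  subjects <- cohort$subjects
  n_raw <- length(met_cols(cohort$metabolites))
  say("input: %d subjects, %d metabolites, %d phenotypes",
      nrow(subjects), n_raw, nrow(cohort$phenotypes))

  covars <- subjects[, default_imputation_covariates(), drop = FALSE]
  prep <- tryCatch(
    preprocess_metabolites(cohort$metabolites, cohort$annotation, covars,
                           m = config$m, n_iter = config$n_iter,
                           k = config$donor_k, seed = config$seed,
                           threshold = config$missingness_threshold),
    error = function(e) stop("[preprocess] ", conditionMessage(e)))
  kept <- met_cols(prep$imputations$datasets[[1]])
  say("preprocess: %d metabolites excluded (>%g%% missing in a batch), %d kept; m = %d imputations",
      nrow(prep$excluded), 100 * config$missingness_threshold,
      length(kept), prep$imputations$m)

  results <- tryCatch(
    run_scan(subjects, prep$imputations, cohort$phenotypes,
             cohort$annotation, models = config$models,
             subgroup = config$subgroup, alpha = config$fdr_alpha),
    error = function(e) stop("[association] ", conditionMessage(e)))
  say("association: %d tests run (%d phenotypes x %d metabolites x %d models), %d significant at FDR<%g (Model 1)",
      nrow(results), nrow(cohort$phenotypes), length(kept),
      length(config$models), sum(results$significant), config$fdr_alpha)

  counts <- count_table(results)
  top <- top_connected(results)
  # empty-set DSC cells are reported in the run log, not as live warnings
  dsc_dom <- withCallingHandlers(
    tryCatch(dsc_matrix(results, "domain"), error = function(e) NULL),
    warning = function(w) {
      log <<- c(log, paste("dsc:", conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
  say("summary: top-connected list of %d metabolites", nrow(top))

  inc <- build_incidence(results, "domain", "subpathway")
  network <- if (length(inc$weights) > 0) {
    list(incidence = inc,
         report = network_report(results, cohort$annotation,
                                 seed = config$seed),
         layout = fr_layout(inc, seed = config$seed))
  } else NULL
  say("network: %d x %d consolidated incidence, %d links",
      nrow(inc$weights), ncol(inc$weights), sum(inc$binary))

  out <- structure(list(results = results, counts = counts, top = top,
                        dsc_domain = dsc_dom, network = network,
                        excluded = prep$excluded, log = log,
                        config = config),
                   class = "atlas_run")
  if (!is.null(config$out_dir) && isTRUE(config$write_outputs)) {
    write_atlas_run(out, config$out_dir)
  }
  out
}

#' Write all atlas outputs under a directory
#'
#' @param run an `atlas_run`.
#' @param dir output directory.
#' @return Invisibly, the directory.
#' @export
write_atlas_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_association_table(run$results, file.path(dir, "associations"))
  utils::write.table(run$counts$per_phenotype,
                     file.path(dir, "counts_per_phenotype.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(run$counts$per_domain,
                     file.path(dir, "counts_per_domain.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(run$top, file.path(dir, "top_connected.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(run$dsc_domain)) {
    utils::write.table(run$dsc_domain, file.path(dir, "dsc_domain.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
  }
  if (!is.null(run$network)) {
    write_network(run$network$incidence, file.path(dir, "network"),
                  seed = run$config$seed)
    jsonlite::write_json(run$network$report,
                         file.path(dir, "network", "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  writeLines(run$log, file.path(dir, "run_log.txt"))
  invisible(dir)
}

#' Read cohort tables previously written by [write_cohort()]
#'
#' @param dir directory holding `subjects.tsv`, `metabolites.tsv`,
#'   `annotation.tsv`, `phenotypes.tsv` (and optionally `truth.tsv`).
#' @return A list shaped like a `sleep_cohort` (without latents).
#' @export
read_cohort <- function(dir) {
  rd <- function(f) utils::read.delim(file.path(dir, f),
                                      check.names = FALSE,
                                      stringsAsFactors = FALSE)
  out <- list(subjects = rd("subjects.tsv"),
              metabolites = rd("metabolites.tsv"),
              annotation = rd("annotation.tsv"),
              phenotypes = rd("phenotypes.tsv"))
  tf <- file.path(dir, "truth.tsv")
  if (file.exists(tf)) out$truth <- utils::read.delim(tf)
  class(out) <- "sleep_cohort"
  out
}
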