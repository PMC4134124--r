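#' Pipeline configuration
#'
#' Assembles and validates the end-to-end configuration. Inputs come either
#' from CSV paths (`registry`, `encounters`, `population`, optionally
#' `standard`) or from a `simulate` block holding [sim_config()] arguments.
#' In the default profile the washout span (1991-1995) immediately precedes
#' the study span (1996-2009), so no incident case can have an unobserved
#' pre-study contact.
#'
#' @param inputs named list of CSV paths, or `NULL` when simulating.
#' @param simulate named list of [sim_config()] arguments, or `NULL`.
#' @param study_span,washout_span integer year pairs.
#' @param gate,weights [gate_rule()] / [score_weights()].
#' @param classification_window_days see [ascertain_cases()].
#' @param reference_year reference level for the trend models.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(inputs = NULL, simulate = NULL,
                            study_span = c(1996L, 2009L),
                            washout_span = c(1991L, 1995L),
                            gate = gate_rule(), weights = score_weights(),
                            classification_window_days = 730,
                            reference_year = 1996L) {
  if (is.null(inputs) && is.null(simulate)) {
    stop_config("inputs", "or `simulate` must be provided")
  }
  cfg <- list(inputs = inputs, simulate = simulate,
              study_span = as.integer(study_span),
              washout_span = as.integer(washout_span),
              gate = gate, weights = weights,
              classification_window_days = classification_window_days,
              reference_year = as.integer(reference_year))
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML (or JSON)
#'
#' YAML is a superset of JSON, so either format parses. Recognised top-level
#' keys: `inputs`, `simulate`, `study_span`, `washout_span`, `gate`,
#' `weights`, `classification_window_days`, `reference_year`.
#'
#' @param path configuration file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("configuration error: config file not found: %s", path),
         call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  pipeline_config(
    inputs = raw$inputs,
    simulate = raw$simulate,
    study_span = unlist(raw$study_span %||% c(1996L, 2009L)),
    washout_span = unlist(raw$washout_span %||% c(1991L, 1995L)),
    gate = do.call(gate_rule, raw$gate %||% list()),
    weights = do.call(score_weights, raw$weights %||% list()),
    classification_window_days = raw$classification_window_days %||% 730,
    reference_year = raw$reference_year %||% 1996L
  )
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full claims-to-trends pipeline
#'
#' Loads (or simulates) the inputs, ascertains incident cases, builds crude
#' and age-standardized rate tables, fits the stratified trend models and
#' writes every output to `out_dir`: `cases.csv`, `rates.csv`, `table2.csv`,
#' `table3.csv`, `trend.csv`, `figure_data/*.csv` and a `run_manifest.json`
#' recording the configuration hash and package version. The run is
#' deterministic given the configuration (including any simulation seed). A
#' `RUN.partial` marker exists while the run is in flight and is removed on
#' success; any stage error halts the run naming the stage.
#'
#' @param config a [pipeline_config()] or path to a YAML/JSON config.
#' @param out_dir output directory (created if absent).
#' @param seed optional override of the simulation seed.
#' @return invisibly, a list with the in-memory `cases`, `rate_table`,
#'   `trend` and file `paths`.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  marker <- file.path(out_dir, "RUN.partial")
  file.create(marker)

  std <- pipeline_stage("standard_population", {
    if (!is.null(config$inputs$standard)) {
      read_standard_population(config$inputs$standard)
    } else {
      canada_2006_standard()
    }
  })

  if (!is.null(config$simulate)) {
    cohort <- pipeline_stage("simulate", {
      args <- config$simulate
      if (!is.null(seed)) args$seed <- seed
      args$calendar_span <- unlist(args$calendar_span %||% config$study_span)
      args$washout_span <- unlist(args$washout_span %||% config$washout_span)
      simulate_cohort(do.call(sim_config, args))
    })
    registry <- cohort$registry
    encounters <- cohort$encounters
    population <- cohort$population
  } else {
    registry <- pipeline_stage("read_registry",
                               read_registry_csv(config$inputs$registry))
    encounters <- pipeline_stage("read_encounters",
                                 read_encounters_csv(config$inputs$encounters))
    population <- pipeline_stage("read_population",
                                 read_population_csv(config$inputs$population))
  }

  cases <- pipeline_stage("ascertain", ascertain_cases(
    registry, encounters, gate = config$gate, weights = config$weights,
    washout_span = config$washout_span, study_span = config$study_span,
    classification_window_days = config$classification_window_days
  ))
  years <- seq(config$study_span[1], config$study_span[2])
  rate_table <- pipeline_stage("rates", build_rate_tables(
    cases, registry, population, std = std, years = years
  ))
  trend <- pipeline_stage("trend", run_trend_suite(
    cases, registry, population, reference_year = config$reference_year,
    years = years
  ))
  table2 <- pipeline_stage("table2", build_table2(cases, registry))
  table3 <- pipeline_stage("table3", build_table3(rate_table))
  figs <- pipeline_stage("figure_data",
                         build_figure_series(rate_table, cases, registry))

  paths <- pipeline_stage("write_outputs", {
    fig_dir <- file.path(out_dir, "figure_data")
    dir.create(fig_dir, showWarnings = FALSE)
    p <- list(
      cases = write_table_csv(cases, file.path(out_dir, "cases.csv")),
      rates = write_table_csv(rate_table, file.path(out_dir, "rates.csv")),
      table2 = write_table_csv(table2, file.path(out_dir, "table2.csv")),
      table3 = write_table_csv(table3, file.path(out_dir, "table3.csv")),
      trend = write_table_csv(trend, file.path(out_dir, "trend.csv"))
    )
    for (nm in names(figs)) {
      p[[paste0("fig_", nm)]] <-
        write_table_csv(figs[[nm]], file.path(fig_dir, paste0(nm, ".csv")))
    }
    p
  })

  pipeline_stage("manifest", {
    cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                                 force = TRUE, digits = NA)
    manifest <- list(
      config = jsonlite::fromJSON(cfg_json, simplifyVector = FALSE),
      config_hash = config_hash(cfg_json),
      seed = seed %||% config$simulate$seed,
      package_version = as.character(utils::packageVersion("ibdclaims")),
      r_version = paste(R.version$major, R.version$minor, sep = ".")
    )
    jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null")
  })

  file.remove(marker)
  invisible(list(cases = cases, rate_table = rate_table, trend = trend,
                 table2 = table2, table3 = table3, figure_series = figs,
                 paths = paths))
}

config_hash <- function(json) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(json, tmp)
  unname(tools::md5sum(tmp))
}
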