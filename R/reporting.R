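#' Result-table writers
#'
#' Canonical CSV emitters (UTF-8, header row, period decimal separator, no
#' currency symbols in numeric columns) for each result surface, plus a run
#' manifest. A thin command-line wrapper over these functions ships at
#' `system.file("cli", "hypocost.R", package = "hypocost")` with subcommands
#' `rates`, `cea`, `dsa`, `psa` and `population`.
#'
#' @name reporting
NULL

write_result_csv <- function(tbl, path) {
  utils::write.csv(as.data.frame(tbl), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Write the incidence-rate table
#'
#' 12 rows (6 strategies x 2 cohorts) with full-precision and 2-dp rates.
#'
#' @param params A `hypocost_params` bundle.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_rates_csv <- function(params, path) {
  write_result_csv(event_rates(params), path)
}

#' Write the per-strategy outcome table
#'
#' A published-style outcome table: rates, costs and QALYs per strategy and
#' cohort. The `cost_inputs` column marks every row's cost columns as
#' conditional on the bundle's unit-cost configuration.
#'
#' @inheritParams write_rates_csv
#' @return `path`, invisibly.
#' @export
write_outcomes_csv <- function(params, path) {
  out <- evaluate_strategies(params) |>
    dplyr::mutate(cost_inputs = "bundle_unit_costs")
  write_result_csv(out, path)
}

#' Write a cost-effectiveness comparison table
#'
#' @inheritParams write_rates_csv
#' @param reference Reference strategy name.
#' @return `path`, invisibly.
#' @export
write_cea_csv <- function(params, reference, path) {
  cmp <- compare_strategies(evaluate_strategies(params), reference,
                            wtp = params$settings$wtp_threshold)
  write_result_csv(cmp, path)
}

#' Write a tornado table
#'
#' @inheritParams write_rates_csv
#' @param strategy,comparator,cohort Passed to [tornado()].
#' @return `path`, invisibly.
#' @export
write_dsa_csv <- function(params, strategy, comparator, cohort, path) {
  write_result_csv(tornado(params, strategy, comparator, cohort), path)
}

#' Write cost-effectiveness acceptability curves
#'
#' @inheritParams write_rates_csv
#' @param cohort Cohort label.
#' @param n_iterations,seed PSA settings.
#' @return `path`, invisibly.
#' @export
write_ceac_csv <- function(params, cohort, path, n_iterations = 1000,
                           seed = NULL) {
  psa <- run_psa(params, cohort, psa_spec(n_iterations, seed = seed))
  write_result_csv(ceac(psa), path)
}

#' Write the population budget-impact table
#'
#' @inheritParams write_rates_csv
#' @return `path`, invisibly.
#' @export
write_population_csv <- function(params, path) {
  write_result_csv(population_costs(params), path)
}

#' Write a run manifest
#'
#' Records the command, configuration path, seed, timestamp, package
#' version and output files of a reporting run as YAML.
#'
#' @param path Manifest output path.
#' @param command Name of the command that ran.
#' @param config Configuration file path used.
#' @param seed Seed used (or `NULL`).
#' @param outputs Character vector of files the run wrote; all must exist.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, command, config, seed, outputs) {
  missing <- outputs[!file.exists(outputs)]
  if (length(missing) > 0) {
    stop("manifest lists outputs that do not exist: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  yaml::write_yaml(list(
    command = command,
    config = config,
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("hypocost")),
    outputs = as.list(outputs)
  ), path)
  invisible(path)
}
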