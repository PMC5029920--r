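#' Parameter bundles
#'
#' All model inputs — cohort clinical profiles, medication strategies, the
#' severity split, resource-use probabilities, risk-equation constants, unit
#' costs, utilities, economic settings and population counts — travel together
#' as a single validated bundle (a nested list of class `hypocost_params`).
#' A bundle carries exactly one country and one currency; outputs inherit
#' them and currencies are never converted silently.
#'
#' Bundles are stored as YAML configuration files. Two fully populated files
#' ship with the package (`us_2015.yaml`, `canada_2015.yaml`); their unit-cost
#' and per-event disutility sections are synthetic plausible defaults (see the
#' file headers) and are meant to be overridden with payer-specific prices.
#'
#' @name parameters
NULL

# sections every bundle must carry
.required_sections <- c(
  "schema", "country", "currency", "cohorts", "strategies", "severity",
  "resource_use", "risk_constants", "unit_costs", "utilities", "settings",
  "population"
)

.strategy_names <- c("metformin", "sulfonylurea", "dpp4", "tzd", "glp1",
                     "basal_insulin")
.cohort_labels <- c("65-79", "80plus")
.unit_cost_fields <- c(
  "gp_visit", "np_visit", "outpatient_visit", "er_visit", "hospitalization",
  "ambulance", "glucagon_kit", "blood_glucose_assay", "smbg_strip",
  "smbg_lancet", "needle", "home_monitor_annual"
)
.severe_branch_names <- c("gp", "np", "outpatient", "er_only", "hospitalization")

#' Load a parameter bundle from a YAML configuration file
#'
#' Reads, validates and returns a full model parameter bundle. Validation is
#' total: every type invariant (ranges, probability sums, required keys) is
#' checked and the first violation raises an error naming the offending field.
#' Keys that are not part of the schema are reported as a warning and dropped.
#'
#' @param path Path to a YAML file with sections `cohorts`, `strategies`,
#'   `severity`, `resource_use`, `risk_constants`, `unit_costs`, `utilities`,
#'   `settings`, `population` plus `schema`, `country` and `currency`.
#' @return A validated bundle of class `hypocost_params`.
#' @seealso [default_parameters()], [write_parameters()], [validate_parameters()]
#' @export
#' @examples
#' p <- load_parameters(system.file("extdata", "us_2015.yaml", package = "hypocost"))
#' p$utilities$u_base
load_parameters <- function(path) {
  if (!file.exists(path)) {
    stop("parameter file not found: ", path, call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  # YAML integers become R integers; the model is double throughout
  raw <- rapply(raw, function(x) if (is.integer(x)) as.double(x) else x,
                how = "replace")
  unknown <- setdiff(names(raw), .required_sections)
  if (length(unknown) > 0) {
    warning("ignoring unknown parameter keys: ",
            paste(unknown, collapse = ", "), call. = FALSE)
    raw <- raw[intersect(names(raw), .required_sections)]
  }
  params <- structure(raw, class = "hypocost_params")
  validate_parameters(params)
  params
}

#' Packaged default parameter bundles
#'
#' Returns the packaged base-case bundle for one country. The two bundles
#' share identical incidence inputs (rates are country-invariant by
#' assumption); they differ in currency, unit costs, drug acquisition costs,
#' the willingness-to-pay threshold and population counts.
#'
#' @param country `"US"` or `"Canada"`.
#' @return A validated bundle of class `hypocost_params`.
#' @export
#' @examples
#' us <- default_parameters("US")
#' us$strategies$basal_insulin$base_rate   # 6.3 events/person-year
default_parameters <- function(country = c("US", "Canada")) {
  country <- match.arg(country)
  file <- switch(country, US = "us_2015.yaml", Canada = "canada_2015.yaml")
  load_parameters(system.file("extdata", file, package = "hypocost"))
}

#' Write a parameter bundle back to YAML
#'
#' Round-trips with [load_parameters()]: saving and re-loading a bundle
#' yields an identical bundle.
#'
#' @param params A `hypocost_params` bundle.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  validate_parameters(params)
  yaml::write_yaml(unclass(params), path, precision = 15)
  invisible(path)
}

#' Validate a parameter bundle
#'
#' Checks every structural and numeric invariant of the bundle: required
#' sections and fields present, probabilities in \[0, 1\], the 95/4/1 severity
#' split and the severe-event branch probabilities each summing to one,
#' clinical covariates inside their admissible ranges, costs non-negative,
#' and a one-year undiscounted horizon. Errors name the failing field.
#'
#' @param params A candidate bundle (nested list).
#' @return `params`, invisibly, if valid.
#' @export
validate_parameters <- function(params) {
  miss <- setdiff(.required_sections, names(params))
  if (length(miss) > 0) {
    fail_field(miss[1], "required section is missing")
  }
  if (!identical(params$schema, "hypocost-params/1")) {
    fail_field("schema", "expected \"hypocost-params/1\"")
  }
  if (!params$country %in% c("US", "Canada")) {
    fail_field("country", "must be \"US\" or \"Canada\"")
  }

  num <- function(x, field, lo = -Inf, hi = Inf, strict_lo = FALSE) {
    if (is.null(x) || !is.numeric(x) || length(x) != 1 || is.na(x)) {
      fail_field(field, "must be a single number")
    }
    if (x < lo || x > hi || (strict_lo && x <= lo)) {
      fail_field(field, sprintf("value %g outside [%g, %g]%s", x, lo, hi,
                                if (strict_lo) " (strict lower bound)" else ""))
    }
    invisible(x)
  }
  prob <- function(x, field) num(x, field, 0, 1)

  # cohorts
  miss <- setdiff(.cohort_labels, names(params$cohorts))
  if (length(miss) > 0) fail_field(paste0("cohorts.", miss[1]), "missing cohort")
  for (lab in names(params$cohorts)) {
    co <- params$cohorts[[lab]]
    pre <- paste0("cohorts.", lab, ".")
    num(co$diabetes_duration, paste0(pre, "diabetes_duration"), 0, Inf, strict_lo = TRUE)
    num(co$hba1c, paste0(pre, "hba1c"), 4, 20)
    num(co$bmi, paste0(pre, "bmi"), 10, 70)
    num(co$gfr, paste0(pre, "gfr"), 0, Inf, strict_lo = TRUE)
  }

  # strategies
  miss <- setdiff(.strategy_names, names(params$strategies))
  if (length(miss) > 0) fail_field(paste0("strategies.", miss[1]), "missing strategy")
  for (nm in names(params$strategies)) {
    st <- params$strategies[[nm]]
    pre <- paste0("strategies.", nm, ".")
    num(st$base_rate, paste0(pre, "base_rate"), 0, Inf, strict_lo = TRUE)
    num(st$daily_smbg_tests, paste0(pre, "daily_smbg_tests"), 0)
    num(st$daily_injections, paste0(pre, "daily_injections"), 0)
    num(st$annual_drug_cost, paste0(pre, "annual_drug_cost"), 0)
  }

  # severity split
  sv <- params$severity
  prob(sv$p_mild, "severity.p_mild")
  prob(sv$p_moderate, "severity.p_moderate")
  prob(sv$p_severe, "severity.p_severe")
  if (abs(sv$p_mild + sv$p_moderate + sv$p_severe - 1) > 1e-8) {
    fail_field("severity", sprintf(
      "p_mild + p_moderate + p_severe = %g, must sum to 1",
      sv$p_mild + sv$p_moderate + sv$p_severe))
  }

  # resource use
  ru <- params$resource_use
  prob(ru$p_hcp_contact, "resource_use.p_hcp_contact")
  prob(ru$p_assay_per_contact, "resource_use.p_assay_per_contact")
  num(ru$n_extra_smbg, "resource_use.n_extra_smbg", 0)
  prob(ru$p_glucagon_moderate, "resource_use.p_glucagon_moderate")
  miss <- setdiff(.severe_branch_names, names(ru$severe_branches))
  if (length(miss) > 0) {
    fail_field(paste0("resource_use.severe_branches.", miss[1]), "missing branch")
  }
  for (br in .severe_branch_names) {
    prob(ru$severe_branches[[br]], paste0("resource_use.severe_branches.", br))
  }
  if (abs(sum(unlist(ru$severe_branches[.severe_branch_names])) - 1) > 1e-8) {
    fail_field("resource_use.severe_branches", "branch probabilities must sum to 1")
  }
  prob(ru$p_glucagon_severe, "resource_use.p_glucagon_severe")
  prob(ru$p_ambulance, "resource_use.p_ambulance")
  prob(ru$p_death_given_hospitalization, "resource_use.p_death_given_hospitalization")

  # risk-equation constants
  rc <- params$risk_constants
  for (f in c("duration_base", "a1c_base", "bmi_base", "gfr_scale")) {
    num(rc[[f]], paste0("risk_constants.", f), 0, Inf, strict_lo = TRUE)
  }
  for (f in c("duration_cap", "duration_offset", "a1c_ref", "bmi_floor",
              "bmi_cap", "bmi_ref", "gfr_exponent", "gfr_floor", "gfr_ref")) {
    num(rc[[f]], paste0("risk_constants.", f))
  }
  if (rc$bmi_floor >= rc$bmi_cap) {
    fail_field("risk_constants.bmi_floor", "floor must be below cap")
  }
  if (rc$gfr_floor >= rc$gfr_ref) {
    fail_field("risk_constants.gfr_floor", "floor must be below the reference cap")
  }
  if (!(rc$gfr_variant %||% "adopted") %in% c("adopted", "printed_div")) {
    fail_field("risk_constants.gfr_variant", "must be \"adopted\" or \"printed_div\"")
  }

  # unit costs
  miss <- setdiff(.unit_cost_fields, names(params$unit_costs))
  if (length(miss) > 0) fail_field(paste0("unit_costs.", miss[1]), "missing unit cost")
  for (f in .unit_cost_fields) {
    num(params$unit_costs[[f]], paste0("unit_costs.", f), 0)
  }

  # utilities
  ut <- params$utilities
  prob(ut$u_base, "utilities.u_base")
  for (f in c("mild_daytime", "mild_nocturnal", "modsev_daytime", "modsev_nocturnal")) {
    num(ut$disutility[[f]], paste0("utilities.disutility.", f), 0)
  }
  prob(ut$p_daytime_mild, "utilities.p_daytime_mild")
  prob(ut$p_daytime_modsev, "utilities.p_daytime_modsev")
  prob(ut$fatal_year_fraction_lost, "utilities.fatal_year_fraction_lost")

  # settings
  se <- params$settings
  num(se$wtp_threshold, "settings.wtp_threshold", 0, Inf, strict_lo = TRUE)
  num(se$exchange_rate_us_to_can, "settings.exchange_rate_us_to_can", 0, Inf,
      strict_lo = TRUE)
  if (!isTRUE(all.equal(se$time_horizon, 1))) {
    fail_field("settings.time_horizon", "the model is annual; must equal 1")
  }
  if (!isTRUE(all.equal(se$discount_rate, 0))) {
    fail_field("settings.discount_rate", "a one-year horizon is undiscounted; must equal 0")
  }

  # population
  po <- params$population
  num(po$n_tight_control_users, "population.n_tight_control_users", 0)
  num(po$rx_ratio_su_to_insulin, "population.rx_ratio_su_to_insulin", 0, Inf,
      strict_lo = TRUE)
  prob(po$share_80plus, "population.share_80plus")

  invisible(params)
}

#' @export
print.hypocost_params <- function(x, ...) {
  cat("<hypocost_params> ", x$country, " (", x$currency, ")\n", sep = "")
  cat("  strategies: ", paste(names(x$strategies), collapse = ", "), "\n", sep = "")
  cat("  cohorts:    ", paste(names(x$cohorts), collapse = ", "), "\n", sep = "")
  cat("  WTP threshold: ", format(x$settings$wtp_threshold, big.mark = ","),
      " per QALY\n", sep = "")
  invisible(x)
}

#' Strategies of a bundle as a tibble
#'
#' @param params A `hypocost_params` bundle.
#' @return A tibble with one row per medication strategy.
#' @export
strategy_table <- function(params) {
  purrr::imap_dfr(params$strategies, function(st, nm) {
    tibble::tibble(
      strategy = nm,
      base_rate = st$base_rate,
      daily_smbg_tests = st$daily_smbg_tests,
      daily_injections = st$daily_injections,
      annual_drug_cost = st$annual_drug_cost
    )
  })
}

#' Cohort clinical profiles as a tibble
#'
#' @param params A `hypocost_params` bundle.
#' @return A tibble with one row per age cohort.
#' @export
cohort_table <- function(params) {
  purrr::imap_dfr(params$cohorts, function(co, lab) {
    tibble::tibble(
      cohort = lab,
      diabetes_duration = co$diabetes_duration,
      hba1c = co$hba1c,
      bmi = co$bmi,
      gfr = co$gfr
    )
  })
}

#' Enumerate scalar parameters of a bundle
#'
#' Flattens the uncertain-parameter sections of a bundle into a tibble of
#' dot-separated paths and base values. This is the default sweep set for the
#' one-way sensitivity analysis and the address space used by [tornado()] and
#' [sample_parameters()].
#'
#' @param params A `hypocost_params` bundle.
#' @param sections Character vector of top-level sections to flatten.
#' @return A tibble with columns `path` and `base`.
#' @export
parameter_table <- function(params,
                            sections = c("strategies", "severity",
                                         "resource_use", "unit_costs",
                                         "utilities")) {
  flatten1 <- function(x, prefix) {
    out <- list()
    for (nm in names(x)) {
      v <- x[[nm]]
      p <- paste0(prefix, nm)
      if (is.list(v)) {
        out <- c(out, flatten1(v, paste0(p, ".")))
      } else if (is.numeric(v) && length(v) == 1) {
        out[[p]] <- v
      }
    }
    out
  }
  leaves <- flatten1(params[sections], "")
  tibble::tibble(path = names(leaves), base = unlist(leaves, use.names = FALSE))
}

# resolve / replace a dot-separated path inside a bundle
get_param <- function(params, path) {
  purrr::pluck(params, !!!strsplit(path, ".", fixed = TRUE)[[1]])
}

set_param <- function(params, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (is.null(get_param(params, path))) {
    stop("unresolvable parameter path: ", path, call. = FALSE)
  }
  purrr::assign_in(params, keys, value)
}
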