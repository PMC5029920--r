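#' Decision-tree expectations
#'
#' The one-year decision tree is evaluated in closed form: per-event expected
#' costs for each severity, annual hypoglycemia and therapy costs, the
#' probability of a fatal hospitalization (Poisson thinning of severe
#' events), and expected QALYs (base utility minus per-event disutilities
#' and the fatality loss). Everything is an expectation, so annual costs are
#' linear in event rates and in every unit cost.
#'
#' @name decision_tree
NULL

#' Expected cost of one mild hypoglycemic event
#'
#' A fraction `p_hcp_contact` of events leads to a primary-care visit with a
#' quantitative glucose assay, and every event triggers `n_extra_smbg`
#' additional self-monitoring tests (one strip and one lancet each).
#'
#' @param resource The `resource_use` section of a parameter bundle.
#' @param costs The `unit_costs` section of a parameter bundle.
#' @return Expected currency per event.
#' @export
event_cost_mild <- function(resource, costs) {
  resource$p_hcp_contact *
    (costs$gp_visit + resource$p_assay_per_contact * costs$blood_glucose_assay) +
    resource$n_extra_smbg * (costs$smbg_strip + costs$smbg_lancet)
}

#' Expected cost of one moderate hypoglycemic event
#'
#' Mild-event follow-up care plus a glucagon injection with probability
#' `p_glucagon_moderate`.
#'
#' @inheritParams event_cost_mild
#' @return Expected currency per event.
#' @export
event_cost_moderate <- function(resource, costs) {
  event_cost_mild(resource, costs) +
    resource$p_glucagon_moderate * costs$glucagon_kit
}

#' Expected cost of one severe hypoglycemic event
#'
#' A severe event takes exactly one management branch (GP, nurse
#' practitioner, outpatient practice, emergency room only, or
#' hospitalization). The transported pathways (ER-only and hospitalization)
#' additionally incur ambulance use with probability `p_ambulance` and a
#' glucagon injection with probability `p_glucagon_severe`. Post-event
#' follow-up (primary-care contact and extra SMBG tests) applies to all
#' severe events, as to every other severity.
#'
#' @inheritParams event_cost_mild
#' @return Expected currency per event.
#' @export
event_cost_severe <- function(resource, costs) {
  br <- resource$severe_branches
  s <- sum(unlist(br[.severe_branch_names]))
  if (abs(s - 1) > 1e-8) {
    fail_field("resource_use.severe_branches",
               sprintf("branch probabilities sum to %g, must sum to 1", s))
  }
  branch <- br$gp * costs$gp_visit +
    br$np * costs$np_visit +
    br$outpatient * costs$outpatient_visit +
    br$er_only * costs$er_visit +
    br$hospitalization * costs$hospitalization
  transported <- br$er_only + br$hospitalization
  ems <- transported * (resource$p_ambulance * costs$ambulance +
                          resource$p_glucagon_severe * costs$glucagon_kit)
  branch + ems + event_cost_mild(resource, costs)
}

#' Per-event cost breakdown by severity
#'
#' @inheritParams event_cost_mild
#' @return A tibble with columns `severity` and `cost`.
#' @export
event_cost_breakdown <- function(resource, costs) {
  tibble::tibble(
    severity = c("mild", "moderate", "severe"),
    cost = c(event_cost_mild(resource, costs),
             event_cost_moderate(resource, costs),
             event_cost_severe(resource, costs))
  )
}

#' Expected annual hypoglycemia cost per person
#'
#' Linearity of expectation over event counts:
#' `mild_rate x mild_cost + moderate_rate x moderate_cost + severe_rate x
#' severe_cost`.
#'
#' @param rates A list or one-row data frame with `mild`, `moderate`,
#'   `severe` event rates (events/person-year), e.g. one row of
#'   [event_rates()].
#' @inheritParams event_cost_mild
#' @return Expected currency per person-year.
#' @export
annual_hypo_cost <- function(rates, resource, costs) {
  rates$mild * event_cost_mild(resource, costs) +
    rates$moderate * event_cost_moderate(resource, costs) +
    rates$severe * event_cost_severe(resource, costs)
}

#' Annual glucose-lowering therapy cost per person
#'
#' Drug acquisition (including dispensing fees) plus daily self-monitoring
#' supplies (strip and lancet per test), needles for injectable therapies,
#' and the annualized home blood-glucose monitor.
#'
#' @param strategy One strategy entry of a bundle.
#' @param costs The `unit_costs` section of a bundle.
#' @return Currency per person-year.
#' @export
annual_therapy_cost <- function(strategy, costs) {
  strategy$annual_drug_cost +
    365 * strategy$daily_smbg_tests * (costs$smbg_strip + costs$smbg_lancet) +
    365 * strategy$daily_injections * costs$needle +
    costs$home_monitor_annual
}

#' Annual probability of fatal hypoglycemia
#'
#' Only hospitalized severe events carry mortality. Treating fatal
#' hospitalizations as thinned Poisson events with intensity
#' `severe_rate x p_hospitalization x p_death_given_hospitalization`, the
#' probability of at least one fatal event in the year is
#' `1 - exp(-intensity)`.
#'
#' @param severe_rate Severe events per person-year. Vectorized.
#' @param resource The `resource_use` section of a bundle.
#' @return Probability in \[0, 1\], monotone in `severe_rate`.
#' @export
fatality_prob <- function(severe_rate, resource) {
  1 - exp(-severe_rate * resource$severe_branches$hospitalization *
            resource$p_death_given_hospitalization)
}

#' Expected annual QALYs per person
#'
#' Base utility for uncomplicated diabetes minus, for each severity class,
#' the event rate times its daytime/nocturnal-weighted disutility, minus the
#' fatality loss (probability of a fatal event times the fraction of the
#' year's base utility forgone). Floored at zero.
#'
#' @param rates A list or one-row data frame with `mild` and
#'   `moderate_severe` rates.
#' @param utilities The `utilities` section of a bundle.
#' @param p_fatal Annual probability of fatal hypoglycemia.
#' @return QALYs per person-year in \[0, u_base\].
#' @export
expected_qaly <- function(rates, utilities, p_fatal = 0) {
  d <- utilities$disutility
  d_mild <- utilities$p_daytime_mild * d$mild_daytime +
    (1 - utilities$p_daytime_mild) * d$mild_nocturnal
  d_modsev <- utilities$p_daytime_modsev * d$modsev_daytime +
    (1 - utilities$p_daytime_modsev) * d$modsev_nocturnal
  q <- utilities$u_base -
    rates$mild * d_mild -
    rates$moderate_severe * d_modsev -
    p_fatal * utilities$fatal_year_fraction_lost * utilities$u_base
  pmax(q, 0)
}

#' Evaluate every strategy and cohort of a bundle
#'
#' Composes the risk equation, severity split, costing, fatality and QALY
#' expectations into one outcome row per strategy and cohort: the package's
#' base-case surface, mirroring a published per-strategy outcome table.
#'
#' @param params A `hypocost_params` bundle.
#' @return A tibble of class `hypocost_outcomes` with columns `strategy`,
#'   `cohort`, `country`, `currency`, the rate columns of [event_rates()],
#'   `annual_hypo_cost`, `annual_therapy_cost`, `annual_total_cost`, `qaly`
#'   and `p_fatal`. Cost columns are conditional on the bundle's unit-cost
#'   configuration (synthetic in the packaged defaults).
#' @export
#' @examples
#' evaluate_strategies(default_parameters("US"))
evaluate_strategies <- function(params) {
  costs <- params$unit_costs
  resource <- params$resource_use
  out <- event_rates(params) |>
    dplyr::mutate(
      country = params$country,
      currency = params$currency,
      annual_hypo_cost = annual_hypo_cost(
        list(mild = .data$mild, moderate = .data$moderate, severe = .data$severe),
        resource, costs),
      annual_therapy_cost = purrr::map_dbl(
        .data$strategy, ~ annual_therapy_cost(params$strategies[[.x]], costs)),
      annual_total_cost = .data$annual_hypo_cost + .data$annual_therapy_cost,
      p_fatal = fatality_prob(.data$severe, resource),
      qaly = expected_qaly(
        list(mild = .data$mild, moderate_severe = .data$moderate_severe),
        params$utilities, .data$p_fatal)
    ) |>
    dplyr::relocate("country", "currency", .after = "cohort")
  class(out) <- c("hypocost_outcomes", class(out))
  out
}
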