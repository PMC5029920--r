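#' Patient-level microsimulation
#'
#' Realizes the decision tree as individual annual event histories: event
#' counts per severity are independent Poisson draws (thinning of a Poisson
#' total by the 95/4/1 severity split), severe events take one of five
#' management branches by successive binomial thinning, resource use
#' (primary-care contacts, glucagon, ambulance) follows the tree's Bernoulli
#' probabilities per event, a hospitalized event is fatal with probability
#' 0.20, and death ends QALY accrual at a uniformly distributed time in the
#' remaining year. Every expectation of the analytic model is therefore a
#' population mean of this generator, which is what makes it an independent
#' Monte-Carlo oracle for the closed-form results and a synthetic-data
#' source for end-to-end tests.
#'
#' @name microsim
NULL

#' Simulate one year of patient-level event histories
#'
#' @param params A `hypocost_params` bundle.
#' @param strategy Strategy name.
#' @param cohort Cohort label.
#' @param n Number of patients (>= 0).
#' @param seed Integer seed; identical seeds give identical collections.
#' @return A tibble of class `hypocost_sim` with one row per patient:
#'   event counts by severity and daytime status, severe-event branch
#'   counts, resource counts, `died`, `hypo_cost`, `therapy_cost`,
#'   `total_cost` and `qaly`. Attributes record the strategy, cohort,
#'   country and seed.
#' @export
#' @examples
#' sim <- simulate_patients(default_parameters("US"), "metformin", "65-79",
#'                          n = 1000, seed = 42)
#' summarize_simulation(sim)
simulate_patients <- function(params, strategy, cohort, n, seed = NULL) {
  stopifnot(strategy %in% names(params$strategies),
            cohort %in% names(params$cohorts), n >= 0)
  if (!is.null(seed)) set.seed(seed)
  st <- params$strategies[[strategy]]
  sv <- params$severity
  ru <- params$resource_use
  br <- ru$severe_branches
  uc <- params$unit_costs
  ut <- params$utilities

  mild_rate <- mild_event_rate(st, params$cohorts[[cohort]],
                               params$risk_constants)
  rates <- split_severity(mild_rate, sv)
  therapy <- annual_therapy_cost(st, uc)

  if (n == 0) {
    out <- tibble::tibble(
      id = integer(), n_mild = integer(), n_moderate = integer(),
      n_severe = integer(), n_day_mild = integer(), n_day_modsev = integer(),
      n_gp = integer(), n_np = integer(), n_outpatient = integer(),
      n_er_only = integer(), n_hospitalization = integer(),
      n_contact = integer(), n_glucagon_moderate = integer(),
      n_glucagon_severe = integer(), n_ambulance = integer(),
      died = logical(), hypo_cost = numeric(), therapy_cost = numeric(),
      total_cost = numeric(), qaly = numeric()
    )
  } else {
    # independent Poisson thinning per severity class
    n_mild <- stats::rpois(n, rates$mild)
    n_moderate <- stats::rpois(n, rates$moderate)
    n_severe <- stats::rpois(n, rates$severe)
    n_events <- n_mild + n_moderate + n_severe

    # severe-event management branch: successive binomial splits of the
    # categorical (gp, np, outpatient, er_only, hospitalization)
    n_gp <- stats::rbinom(n, n_severe, br$gp)
    rem <- n_severe - n_gp
    n_np <- stats::rbinom(n, rem, br$np / (1 - br$gp))
    rem <- rem - n_np
    n_out <- stats::rbinom(n, rem, br$outpatient / (1 - br$gp - br$np))
    rem <- rem - n_out
    n_er <- stats::rbinom(n, rem,
                          br$er_only / (br$er_only + br$hospitalization))
    n_hosp <- rem - n_er

    # per-event resource draws
    n_contact <- stats::rbinom(n, n_events, ru$p_hcp_contact)
    n_assay <- stats::rbinom(n, n_contact, ru$p_assay_per_contact)
    n_gluc_mod <- stats::rbinom(n, n_moderate, ru$p_glucagon_moderate)
    transported <- n_er + n_hosp
    n_gluc_sev <- stats::rbinom(n, transported, ru$p_glucagon_severe)
    n_amb <- stats::rbinom(n, transported, ru$p_ambulance)

    n_fatal <- stats::rbinom(n, n_hosp, ru$p_death_given_hospitalization)
    died <- n_fatal > 0

    hypo_cost <- n_contact * uc$gp_visit + n_assay * uc$blood_glucose_assay +
      ru$n_extra_smbg * n_events * (uc$smbg_strip + uc$smbg_lancet) +
      n_gluc_mod * uc$glucagon_kit +
      n_gp * uc$gp_visit + n_np * uc$np_visit + n_out * uc$outpatient_visit +
      n_er * uc$er_visit + n_hosp * uc$hospitalization +
      n_amb * uc$ambulance + n_gluc_sev * uc$glucagon_kit

    n_day_mild <- stats::rbinom(n, n_mild, ut$p_daytime_mild)
    n_modsev <- n_moderate + n_severe
    n_day_modsev <- stats::rbinom(n, n_modsev, ut$p_daytime_modsev)
    d <- ut$disutility
    death_loss <- ifelse(died, stats::runif(n) * ut$u_base, 0)
    qaly <- ut$u_base -
      n_day_mild * d$mild_daytime -
      (n_mild - n_day_mild) * d$mild_nocturnal -
      n_day_modsev * d$modsev_daytime -
      (n_modsev - n_day_modsev) * d$modsev_nocturnal -
      death_loss

    out <- tibble::tibble(
      id = seq_len(n), n_mild = n_mild, n_moderate = n_moderate,
      n_severe = n_severe, n_day_mild = n_day_mild,
      n_day_modsev = n_day_modsev, n_gp = n_gp, n_np = n_np,
      n_outpatient = n_out, n_er_only = n_er, n_hospitalization = n_hosp,
      n_contact = n_contact, n_glucagon_moderate = n_gluc_mod,
      n_glucagon_severe = n_gluc_sev, n_ambulance = n_amb,
      died = died, hypo_cost = hypo_cost, therapy_cost = therapy,
      total_cost = hypo_cost + therapy, qaly = qaly
    )
  }
  class(out) <- c("hypocost_sim", class(out))
  attr(out, "strategy") <- strategy
  attr(out, "cohort") <- cohort
  attr(out, "country") <- params$country
  attr(out, "seed") <- seed
  out
}

#' Summary statistics of a simulated cohort
#'
#' Means, standard deviations and standard errors for costs, QALYs and
#' event counts, plus the realized severity proportions and the
#' hospitalization share of severe events.
#'
#' @param sim A `hypocost_sim` collection from [simulate_patients()].
#' @return A list with elements `stats` (tibble: `quantity`, `mean`, `sd`,
#'   `se`, `ci_lo`, `ci_hi`), `severity_proportions` (named vector over
#'   mild/moderate/severe), `p_hospitalization_given_severe` and `p_died`.
#' @export
summarize_simulation <- function(sim) {
  if (nrow(sim) == 0) stop("empty simulated collection", call. = FALSE)
  one <- function(quantity, x) {
    m <- mean(x); s <- stats::sd(x); se <- s / sqrt(length(x))
    tibble::tibble(quantity = quantity, mean = m, sd = s, se = se,
                   ci_lo = m - 1.96 * se, ci_hi = m + 1.96 * se)
  }
  stats_tbl <- dplyr::bind_rows(
    one("hypo_cost", sim$hypo_cost),
    one("total_cost", sim$total_cost),
    one("qaly", sim$qaly),
    one("n_mild", sim$n_mild),
    one("n_moderate", sim$n_moderate),
    one("n_severe", sim$n_severe)
  )
  n_events <- sum(sim$n_mild) + sum(sim$n_moderate) + sum(sim$n_severe)
  sev_prop <- if (n_events > 0) {
    c(mild = sum(sim$n_mild), moderate = sum(sim$n_moderate),
      severe = sum(sim$n_severe)) / n_events
  } else {
    c(mild = NA_real_, moderate = NA_real_, severe = NA_real_)
  }
  p_hosp <- if (sum(sim$n_severe) > 0) {
    sum(sim$n_hospitalization) / sum(sim$n_severe)
  } else {
    NA_real_
  }
  list(
    stats = stats_tbl,
    severity_proportions = sev_prop,
    p_hospitalization_given_severe = p_hosp,
    p_died = mean(sim$died)
  )
}
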