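#' Population budget impact
#'
#' Scales the per-person model outputs to the national cohort of older
#' adults attaining very tight glycemic control (HbA1c < 6.5%) with insulin
#' or sulfonylureas, and prices three disinvestment scenarios. All outputs
#' are exactly linear in user counts; person counts are rounded to the
#' nearest integer with the remainder assigned so partitions sum exactly.
#'
#' @name population
NULL

#' Split tight-control users into insulin and sulfonylurea users
#'
#' With a prescription ratio `ratio` of sulfonylurea to insulin users,
#' insulin users are `round(n_total / (1 + ratio))` and sulfonylurea users
#' the remainder.
#'
#' @param n_total Total number of users (>= 0).
#' @param ratio Sulfonylurea-to-insulin prescription ratio (> 0).
#' @return A one-row tibble with columns `basal_insulin` and `sulfonylurea`.
#' @export
#' @examples
#' split_users(128626, 2.3)  # 38,978 insulin and 89,648 sulfonylurea users
split_users <- function(n_total, ratio) {
  stopifnot(n_total >= 0, ratio > 0)
  ins <- round(n_total / (1 + ratio))
  tibble::tibble(basal_insulin = ins, sulfonylurea = n_total - ins)
}

#' Partition users into the two age cohorts
#'
#' @param n Number of users (>= 0).
#' @param share_80plus Fraction aged 80 and older, in \[0, 1\].
#' @return A tibble with columns `cohort` (`"65-79"`, `"80plus"`) and `n`,
#'   summing exactly to `n`.
#' @export
age_partition <- function(n, share_80plus) {
  stopifnot(share_80plus >= 0, share_80plus <= 1, n >= 0)
  n80 <- round(share_80plus * n)
  tibble::tibble(cohort = c("65-79", "80plus"), n = c(n - n80, n80))
}

# user counts by drug and cohort for a bundle's population block
population_users <- function(params) {
  po <- params$population
  drugs <- split_users(po$n_tight_control_users, po$rx_ratio_su_to_insulin)
  purrr::map_dfr(c("basal_insulin", "sulfonylurea"), function(d) {
    dplyr::mutate(age_partition(drugs[[d]], po$share_80plus),
                  strategy = d, .before = 1)
  })
}

#' National annual cost of insulin- and sulfonylurea-induced hypoglycemia
#'
#' User counts by drug and cohort times per-person annual costs from the
#' decision tree. The hypoglycemia-attributable component (`hypo_cost`) is
#' the headline population cost; the therapy component and total are
#' reported alongside because disinvestment arithmetic needs them.
#'
#' @param params A `hypocost_params` bundle.
#' @param outcomes Optionally, pre-computed [evaluate_strategies()] output
#'   for `params`.
#' @return A tibble with one row per drug and cohort plus a `combined`
#'   summary row (`strategy = "combined"`), columns `users`, `hypo_cost`,
#'   `therapy_cost`, `total_cost` (currency/year).
#' @export
#' @examples
#' population_costs(default_parameters("Canada"))
population_costs <- function(params, outcomes = NULL) {
  outcomes <- outcomes %||% evaluate_strategies(params)
  users <- population_users(params)
  per <- users |>
    dplyr::left_join(
      dplyr::select(outcomes, "strategy", "cohort",
                    "annual_hypo_cost", "annual_therapy_cost"),
      by = c("strategy", "cohort")
    )
  if (anyNA(per$annual_hypo_cost)) {
    stop("outcomes are missing a drug/cohort cell needed for the population model",
         call. = FALSE)
  }
  per <- per |>
    dplyr::mutate(
      country = params$country,
      users = .data$n,
      hypo_cost = .data$n * .data$annual_hypo_cost,
      therapy_cost = .data$n * .data$annual_therapy_cost,
      total_cost = .data$hypo_cost + .data$therapy_cost
    ) |>
    dplyr::select("country", "strategy", "cohort", "users",
                  "hypo_cost", "therapy_cost", "total_cost")
  combined <- per |>
    dplyr::summarise(
      country = params$country, strategy = "combined", cohort = "all",
      users = sum(.data$users), hypo_cost = sum(.data$hypo_cost),
      therapy_cost = sum(.data$therapy_cost),
      total_cost = sum(.data$total_cost)
    )
  dplyr::bind_rows(per, combined)
}

#' Define a disinvestment scenario
#'
#' @param kind `"no_replacement"` (stop insulin/sulfonylurea therapy with no
#'   substitute), `"single_replacement"` (switch every user to one
#'   strategy), or `"fifty_fifty_mix"` (switch to a 50/50 mix of two
#'   strategies).
#' @param replacements Character vector of replacement strategy names:
#'   none, one, or two according to `kind`.
#' @return A list of class `hypocost_scenario`.
#' @export
#' @examples
#' disinvestment_scenario("fifty_fifty_mix", c("metformin", "tzd"))
disinvestment_scenario <- function(kind = c("no_replacement",
                                            "single_replacement",
                                            "fifty_fifty_mix"),
                                   replacements = character()) {
  kind <- match.arg(kind)
  need <- switch(kind, no_replacement = 0, single_replacement = 1,
                 fifty_fifty_mix = 2)
  if (length(replacements) != need) {
    stop(sprintf("scenario `%s` needs %d replacement strateg%s, got %d",
                 kind, need, if (need == 1) "y" else "ies",
                 length(replacements)), call. = FALSE)
  }
  structure(list(kind = kind, replacements = replacements),
            class = "hypocost_scenario")
}

#' Annual savings from a disinvestment scenario
#'
#' Current users' total annual cost (therapy plus hypoglycemia) minus the
#' total cost of the replacement mix for the same user counts; with no
#' replacement, the whole current cost is saved.
#'
#' @param params A `hypocost_params` bundle.
#' @param scenario A [disinvestment_scenario()].
#' @param outcomes Optionally, pre-computed [evaluate_strategies()] output.
#' @return A one-row tibble with `country`, `kind`, `replacements`,
#'   `current_cost`, `replacement_cost`, `savings` (currency/year).
#' @export
#' @examples
#' disinvestment_savings(default_parameters("US"),
#'                       disinvestment_scenario("single_replacement", "metformin"))
disinvestment_savings <- function(params, scenario, outcomes = NULL) {
  stopifnot(inherits(scenario, "hypocost_scenario"))
  outcomes <- outcomes %||% evaluate_strategies(params)
  unknown <- setdiff(scenario$replacements, names(params$strategies))
  if (length(unknown) > 0) {
    stop("unknown replacement strategy: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  users <- population_users(params)
  total_cost_for <- function(counts) {
    cell <- dplyr::left_join(
      counts,
      dplyr::select(outcomes, "strategy", "cohort", "annual_total_cost"),
      by = c("strategy", "cohort"))
    sum(cell$n * cell$annual_total_cost)
  }
  current <- total_cost_for(users)
  replacement <- if (scenario$kind == "no_replacement") 0 else {
    mix <- purrr::map_dbl(scenario$replacements, function(nm) {
      total_cost_for(dplyr::mutate(users, strategy = nm))
    })
    mean(mix)  # 100% of one strategy, or the 50/50 average of two
  }
  tibble::tibble(
    country = params$country,
    kind = scenario$kind,
    replacements = paste(scenario$replacements, collapse = "+"),
    current_cost = current,
    replacement_cost = replacement,
    savings = current - replacement
  )
}
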