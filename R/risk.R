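#' Hypoglycemia risk equation
#'
#' Annual mild-hypoglycemia incidence is predicted by a multiplicative
#' equation: a medication-class base rate times four dimensionless risk
#' multipliers for diabetes duration, HbA1c, body mass index and glomerular
#' filtration rate. Each multiplier equals 1 at its reference value and is
#' clamped flat outside its supported covariate range. Moderate and severe
#' events are added on top of the mild rate so that the severity distribution
#' of all events is 95% mild, 4% moderate, 1% severe.
#'
#' @name risk_model
NULL

#' Duration risk multiplier
#'
#' `duration_base ^ (min(duration, duration_cap) - duration_offset)`:
#' risk grows ~3.7%/year of diabetes duration, capped at 20 years, relative
#' to a 9-year reference.
#'
#' @param duration Diabetes duration in years (> 0). Vectorized.
#' @param constants The `risk_constants` section of a parameter bundle.
#' @return Dimensionless multiplier (> 0).
#' @export
#' @examples
#' rc <- default_parameters("US")$risk_constants
#' risk_duration(c(9, 15.6, 25), rc)
risk_duration <- function(duration, constants) {
  if (any(duration <= 0)) {
    fail_field("duration", "diabetes duration must be positive")
  }
  constants$duration_base ^
    (pmin(duration, constants$duration_cap) - constants$duration_offset)
}

#' HbA1c risk multiplier
#'
#' `a1c_base ^ (hba1c - a1c_ref)`: strictly decreasing in HbA1c (tighter
#' glycemic control raises hypoglycemia risk).
#'
#' @param hba1c Glycated hemoglobin in percent. Vectorized.
#' @inheritParams risk_duration
#' @return Dimensionless multiplier (> 0).
#' @export
risk_hba1c <- function(hba1c, constants) {
  constants$a1c_base ^ (hba1c - constants$a1c_ref)
}

#' Body-mass-index risk multiplier
#'
#' `bmi_base ^ (clamp(bmi, bmi_floor, bmi_cap) - bmi_ref)`: non-increasing
#' in BMI, flat below 21 and above 35 kg/m².
#'
#' @param bmi Body mass index in kg/m². Vectorized.
#' @inheritParams risk_duration
#' @return Dimensionless multiplier (> 0).
#' @export
risk_bmi <- function(bmi, constants) {
  constants$bmi_base ^
    (clamp(bmi, constants$bmi_floor, constants$bmi_cap) - constants$bmi_ref)
}

#' Glomerular-function risk multiplier
#'
#' `gfr_scale ^ (clamp(gfr, gfr_floor, gfr_ref)^gfr_exponent - gfr_ref^gfr_exponent)`:
#' equals 1 for GFR at or above 60 ml/min and rises as renal function
#' declines, flat below 15 ml/min. The source expression for this multiplier
#' is typographically ambiguous; this reading is the only one consistent with
#' the published incidence table and is the default (`gfr_variant =
#' "adopted"`). The alternative reading that divides the multiplier by 1.2
#' (`gfr_variant = "printed_div"`) is available for audit.
#'
#' @param gfr Glomerular filtration rate in ml/min (> 0). Vectorized.
#' @inheritParams risk_duration
#' @return Dimensionless multiplier (>= 1 under the adopted reading).
#' @export
risk_gfr <- function(gfr, constants) {
  if (any(gfr <= 0)) {
    fail_field("gfr", "glomerular filtration rate must be positive")
  }
  g <- clamp(gfr, constants$gfr_floor, constants$gfr_ref)
  m <- constants$gfr_scale ^
    (g ^ constants$gfr_exponent - constants$gfr_ref ^ constants$gfr_exponent)
  if (identical(constants$gfr_variant %||% "adopted", "printed_div")) m <- m / 1.2
  m
}

#' Annual mild-hypoglycemia rate for one strategy and cohort
#'
#' Base rate of the medication class times the four risk multipliers
#' evaluated at the cohort's average clinical profile.
#'
#' @param strategy One strategy entry of a bundle (list with `base_rate`), or
#'   a strategy name to be looked up in `params`.
#' @param cohort One cohort entry of a bundle (list with `diabetes_duration`,
#'   `hba1c`, `bmi`, `gfr`), or a cohort label to be looked up in `params`.
#' @param constants The `risk_constants` section of a bundle (ignored when
#'   `params` is given).
#' @param params Optionally, a full `hypocost_params` bundle used to resolve
#'   names and constants.
#' @return Mild events per person-year (> 0).
#' @export
#' @examples
#' p <- default_parameters("US")
#' mild_event_rate("metformin", "65-79", params = p)   # 1.3736
mild_event_rate <- function(strategy, cohort, constants = NULL, params = NULL) {
  if (!is.null(params)) {
    if (is.character(strategy)) strategy <- params$strategies[[strategy]]
    if (is.character(cohort)) cohort <- params$cohorts[[cohort]]
    constants <- constants %||% params$risk_constants
  }
  strategy$base_rate *
    risk_duration(cohort$diabetes_duration, constants) *
    risk_hba1c(cohort$hba1c, constants) *
    risk_bmi(cohort$bmi, constants) *
    risk_gfr(cohort$gfr, constants)
}

#' Split a mild rate into the full severity spectrum
#'
#' The risk equation predicts the mild rate; moderate and severe events are
#' added so that all events split `p_mild : p_moderate : p_severe`
#' (default 95/4/1). Hence `moderate_severe = mild * (p_moderate + p_severe)
#' / p_mild` and `total = mild / p_mild`.
#'
#' @param mild Mild events per person-year (>= 0). Vectorized.
#' @param severity The `severity` section of a bundle.
#' @return A tibble with columns `mild`, `moderate`, `severe`,
#'   `moderate_severe`, `total`.
#' @export
#' @examples
#' split_severity(1.3736, default_parameters("US")$severity)
split_severity <- function(mild, severity) {
  if (any(mild < 0)) fail_field("mild", "rates must be non-negative")
  if (severity$p_mild <= 0) fail_field("severity.p_mild", "must be positive")
  tibble::tibble(
    mild = mild,
    moderate = mild * severity$p_moderate / severity$p_mild,
    severe = mild * severity$p_severe / severity$p_mild,
    moderate_severe = moderate + severe,
    total = mild / severity$p_mild
  )
}

#' Incidence-rate table for all strategies and cohorts
#'
#' The package's rate surface: one row per medication strategy and age
#' cohort, with the mild rate from the risk equation and the derived
#' moderate, severe and total rates. `mild_2dp`, `moderate_severe_2dp` and
#' `total_2dp` carry the half-up-rounded values used when mirroring published
#' tables; the published headline totals are formed by summing the two
#' independently rounded components.
#'
#' @param params A `hypocost_params` bundle.
#' @return A tibble with 12 rows (6 strategies x 2 cohorts).
#' @export
#' @examples
#' event_rates(default_parameters("US"))
event_rates <- function(params) {
  grid <- tidyr::expand_grid(
    strategy = names(params$strategies),
    cohort = names(params$cohorts)
  )
  rates <- purrr::map2_dfr(grid$strategy, grid$cohort, function(st, co) {
    mild <- mild_event_rate(params$strategies[[st]], params$cohorts[[co]],
                            params$risk_constants)
    split_severity(mild, params$severity)
  })
  dplyr::bind_cols(grid, rates) |>
    dplyr::mutate(
      mild_2dp = round_half_up(.data$mild, 2),
      moderate_severe_2dp = round_half_up(.data$moderate_severe, 2),
      total_2dp = .data$mild_2dp + .data$moderate_severe_2dp
    )
}
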