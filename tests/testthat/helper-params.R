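# shared fixtures: packaged bundles (loaded once) and a hand-priced unit-cost
# table whose expectations are easy to evaluate on paper
us_params <- local({
  p <- NULL
  function() {
    if (is.null(p)) p <<- default_parameters("US")
    p
  }
})

canada_params <- local({
  p <- NULL
  function() {
    if (is.null(p)) p <<- default_parameters("Canada")
    p
  }
})

toy_costs <- list(
  gp_visit = 100, np_visit = 80, outpatient_visit = 150, er_visit = 500,
  hospitalization = 10000, ambulance = 400, glucagon_kit = 200,
  blood_glucose_assay = 10, smbg_strip = 1, smbg_lancet = 0.5,
  needle = 0.2, home_monitor_annual = 50
)

zero_costs <- lapply(toy_costs, function(x) 0)

# one outcome row by strategy/cohort (and country if present)
outcome_row <- function(outcomes, strategy, cohort, country = NULL) {
  r <- outcomes[outcomes$strategy == strategy & outcomes$cohort == cohort, ]
  if (!is.null(country)) r <- r[r$country == country, ]
  r
}
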