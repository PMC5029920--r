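ru <- function() us_params()$resource_use

test_that("per-event expected costs match hand-evaluated expectations", {
  r <- ru()
  expect_equal(event_cost_mild(r, zero_costs), 0)
  expect_equal(event_cost_severe(r, zero_costs), 0)

  # 0.14 x (100 + 10) + 3.9 x 1.5
  expect_equal(event_cost_mild(r, toy_costs), 21.25)
  # + 0.02 x 200
  expect_equal(event_cost_moderate(r, toy_costs), 25.25)
  # branch 2551.4 + EMS (0.17+0.24) x (400 + 0.25 x 200) + follow-up 21.25
  expect_equal(event_cost_severe(r, toy_costs), 2757.15)

  # degenerate: glucagon free makes moderate equal mild
  c2 <- toy_costs; c2$glucagon_kit <- 0
  expect_equal(event_cost_moderate(r, c2), event_cost_mild(r, c2))

  # degenerate: certain hospitalization recovers hosp + ambulance +
  # 0.25 glucagon + follow-up
  r2 <- r
  r2$severe_branches <- list(gp = 0, np = 0, outpatient = 0, er_only = 0,
                             hospitalization = 1)
  expect_equal(event_cost_severe(r2, toy_costs),
               10000 + 400 + 0.25 * 200 + 21.25)

  # linearity: doubling every unit cost doubles each per-event cost
  dbl <- lapply(toy_costs, function(x) 2 * x)
  expect_equal(event_cost_mild(r, dbl), 2 * event_cost_mild(r, toy_costs))
  expect_equal(event_cost_severe(r, dbl), 2 * event_cost_severe(r, toy_costs))

  # ordering under any table where severe branches are costlier than follow-up
  expect_true(event_cost_severe(r, toy_costs) >=
                event_cost_moderate(r, toy_costs))
  expect_true(event_cost_moderate(r, toy_costs) >=
                event_cost_mild(r, toy_costs))

  r3 <- r; r3$severe_branches$hospitalization <- 0.5
  expect_error(event_cost_severe(r3, toy_costs), "severe_branches")
})

test_that("annual hypoglycemia cost is the rate-weighted event cost", {
  r <- ru()
  expect_equal(annual_hypo_cost(list(mild = 0, moderate = 0, severe = 0),
                                r, toy_costs), 0)
  expect_equal(
    annual_hypo_cost(list(mild = 1, moderate = 0.04, severe = 0.01),
                     r, toy_costs),
    21.25 + 0.04 * 25.25 + 0.01 * 2757.15
  )
})

test_that("annual hypoglycemia cost is linear in every unit cost", {
  r <- ru()
  rates <- list(mild = 1.37, moderate = 0.058, severe = 0.014)
  base <- annual_hypo_cost(rates, r, toy_costs)
  set.seed(11)
  for (f in names(toy_costs)) {
    for (delta in stats::runif(2, 0.5, 3)) {
      perturbed <- toy_costs
      perturbed[[f]] <- toy_costs[[f]] * delta
      slope1 <- annual_hypo_cost(rates, r, perturbed) - base
      perturbed[[f]] <- toy_costs[[f]] * (1 + 2 * (delta - 1))
      slope2 <- annual_hypo_cost(rates, r, perturbed) - base
      expect_equal(slope2, 2 * slope1, tolerance = 1e-9)
    }
  }
})

test_that("therapy cost adds drug, monitoring, needles and the monitor", {
  st <- list(base_rate = 1, daily_smbg_tests = 2.08, daily_injections = 1,
             annual_drug_cost = 300)
  costs <- list(smbg_strip = 1, smbg_lancet = 0.5, needle = 0.2,
                home_monitor_annual = 50)
  expect_equal(annual_therapy_cost(st, costs),
               300 + 365 * 2.08 * 1.5 + 365 * 0.2 + 50)  # 1561.8
  st0 <- list(base_rate = 1, daily_smbg_tests = 0, daily_injections = 0,
              annual_drug_cost = 0)
  expect_equal(annual_therapy_cost(st0, zero_costs), 0)

  # metformin and dpp4 differ only in drug acquisition cost
  p <- us_params()
  d <- annual_therapy_cost(p$strategies$dpp4, p$unit_costs) -
    annual_therapy_cost(p$strategies$metformin, p$unit_costs)
  expect_equal(d, p$strategies$dpp4$annual_drug_cost -
                 p$strategies$metformin$annual_drug_cost)
})

test_that("fatality probability is the thinned-Poisson closed form", {
  r <- ru()
  expect_equal(fatality_prob(0, r), 0)
  expect_equal(fatality_prob(0.01, r), 1 - exp(-0.01 * 0.24 * 0.20))
  expect_equal(fatality_prob(1e9, r), 1)
  x <- seq(0, 5, by = 0.25)
  expect_true(all(diff(fatality_prob(x, r)) > 0))
  expect_true(all(fatality_prob(x, r) >= 0 & fatality_prob(x, r) <= 1))
})

test_that("expected QALYs start at base utility and fall with events", {
  ut <- us_params()$utilities
  expect_equal(expected_qaly(list(mild = 0, moderate_severe = 0), ut, 0),
               0.844)
  q1 <- expected_qaly(list(mild = 1.37, moderate_severe = 0.072), ut, 0.001)
  expect_lt(q1, 0.844)

  # doubling every disutility weakly decreases the result
  ut2 <- ut
  ut2$disutility <- lapply(ut$disutility, function(x) 2 * x)
  expect_lt(expected_qaly(list(mild = 1.37, moderate_severe = 0.072), ut2, 0.001),
            q1)

  # floored at zero under absurd rates
  expect_equal(expected_qaly(list(mild = 1e5, moderate_severe = 1e4), ut, 1), 0)
})

test_that("evaluate_strategies produces a coherent 12-row surface per country", {
  for (p in list(us_params(), canada_params())) {
    out <- evaluate_strategies(p)
    expect_equal(nrow(out), 12)
    expect_true(all(out$country == p$country))
    expect_equal(out$annual_total_cost,
                 out$annual_hypo_cost + out$annual_therapy_cost)
    expect_true(all(out$qaly >= 0 & out$qaly <= p$utilities$u_base))
    expect_true(all(out$p_fatal >= 0 & out$p_fatal <= 1))
    expect_true(all(out$annual_hypo_cost > 0))

    # metformin, dpp4 and tzd share rates and QALYs within a cohort
    for (co in c("65-79", "80plus")) {
      trio <- out[out$strategy %in% c("metformin", "dpp4", "tzd") &
                    out$cohort == co, ]
      expect_equal(length(unique(trio$mild)), 1)
      expect_equal(length(unique(trio$qaly)), 1)
    }

    # QALY ordering mirrors event-rate ordering
    for (co in c("65-79", "80plus")) {
      g <- out[out$cohort == co, ]
      expect_lt(outcome_row(g, "basal_insulin", co)$qaly,
                outcome_row(g, "sulfonylurea", co)$qaly)
      expect_lt(outcome_row(g, "sulfonylurea", co)$qaly,
                outcome_row(g, "metformin", co)$qaly)
      expect_equal(order(g$total), order(-g$qaly))
    }

    # 80plus carries more events, hence fewer QALYs, than 65-79
    for (st in names(p$strategies)) {
      expect_lt(outcome_row(out, st, "80plus")$qaly,
                outcome_row(out, st, "65-79")$qaly)
    }
  }
})
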