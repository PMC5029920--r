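test_that("PSA draws are reproducible and moment-matched", {
  p <- us_params()
  s <- psa_spec(50, seed = 123)
  d1 <- sample_parameters(p, s)
  d2 <- sample_parameters(p, s)
  expect_identical(d1, d2)                      # determinism contract
  expect_equal(nrow(d1), 50)

  # gamma parameters: sample mean within 1% of base at 10,000 draws
  big <- sample_parameters(p, psa_spec(10000, seed = 7))
  for (path in c("strategies.basal_insulin.base_rate",
                 "unit_costs.hospitalization",
                 "utilities.disutility.modsev_daytime")) {
    base <- hypocost:::get_param(p, path)
    expect_equal(mean(big[[path]]), base, tolerance = 0.01)
    expect_equal(stats::sd(big[[path]]), 0.25 * base / 1.96, tolerance = 0.05)
    expect_true(all(big[[path]] > 0))
  }
  # beta-distributed base utility stays in (0, 1]
  expect_true(all(big[["utilities.u_base"]] > 0 &
                    big[["utilities.u_base"]] <= 1))
  expect_equal(mean(big[["utilities.u_base"]]), 0.844, tolerance = 0.01)

  # a zero-valued cost cannot carry a gamma distribution: fixed with warning
  p0 <- hypocost:::set_param(p, "unit_costs.home_monitor_annual", 0)
  expect_warning(d0 <- sample_parameters(p0, psa_spec(20, seed = 1)),
                 "home_monitor_annual")
  expect_true(all(d0[["unit_costs.home_monitor_annual"]] == 0))
})

test_that("zero-variance PSA collapses to the base case", {
  p <- us_params()
  psa <- run_psa(p, "65-79", psa_spec(1, seed = 5, range_fraction = 0))
  base <- evaluate_strategies(p)
  base <- base[base$cohort == "65-79", ]
  m <- merge(as.data.frame(psa$draws), as.data.frame(base), by = "strategy")
  expect_equal(m$cost, m$annual_total_cost, tolerance = 1e-12)
  expect_equal(m$qaly.x, m$qaly.y, tolerance = 1e-12)
})

test_that("PSA outputs have the right shape and are seed-deterministic", {
  p <- canada_params()
  a <- run_psa(p, "80plus", psa_spec(40, seed = 99))
  b <- run_psa(p, "80plus", psa_spec(40, seed = 99))
  expect_identical(a$draws, b$draws)
  expect_equal(nrow(a$draws), 40 * 6)
  expect_equal(sort(unique(a$draws$strategy)), sort(names(p$strategies)))
  expect_true(all(a$draws$cost > 0))
  expect_true(all(a$draws$qaly >= 0 & a$draws$qaly <= 1))
})

test_that("the base-case ICER sits inside the sampled ICER distribution", {
  p <- us_params()
  psa <- run_psa(p, "65-79", psa_spec(400, seed = 31))
  d <- tidyr::pivot_wider(psa$draws, names_from = "strategy",
                          values_from = c("cost", "qaly"))
  samp <- (d$cost_dpp4 - d$cost_sulfonylurea) /
    (d$qaly_dpp4 - d$qaly_sulfonylurea)
  base <- evaluate_strategies(p)
  base <- base[base$cohort == "65-79", ]
  base_icer <- icer(base[base$strategy == "dpp4", ],
                    base[base$strategy == "sulfonylurea", ])$icer
  q <- stats::quantile(samp, c(0.025, 0.975))
  expect_gt(base_icer, q[[1]])
  expect_lt(base_icer, q[[2]])
})

test_that("acceptability curves are proper probabilities", {
  p <- us_params()
  psa <- run_psa(p, "65-79", psa_spec(200, seed = 17))
  cc <- ceac(psa, wtp_grid = seq(0, 2 * p$settings$wtp_threshold,
                                 length.out = 21))
  sums <- tapply(cc$probability, cc$wtp, sum)
  expect_equal(as.numeric(sums), rep(1, 21))

  # at WTP 0 the cheapest strategy (metformin) wins
  at0 <- cc[cc$wtp == 0, ]
  expect_equal(at0$strategy[which.max(at0$probability)], "metformin")

  # widely dominated strategies have essentially no acceptability anywhere
  ins <- cc[cc$strategy %in% c("basal_insulin", "glp1"), ]
  expect_true(all(ins$probability < 0.01))

  expect_error(ceac(psa, wtp_grid = c(1, 1, 2)), "increasing")
})

test_that("tornado entries respect ranges, sorting and monotonicity", {
  p <- us_params()
  params <- tibble::tibble(
    path = c("strategies.dpp4.annual_drug_cost",
             "unit_costs.hospitalization",
             "utilities.u_base"),
    low = NA_real_, high = NA_real_
  )
  params$low <- purrr::map_dbl(params$path, ~ 0.75 * hypocost:::get_param(p, .x))
  params$high <- purrr::map_dbl(params$path, ~ 1.25 * hypocost:::get_param(p, .x))
  tor <- tornado(p, "dpp4", "sulfonylurea", "65-79", parameters = params)
  expect_s3_class(tor, "hypocost_dsa")
  expect_equal(nrow(tor), 3)
  expect_true(all(diff(tor$spread) <= 0))

  # the dpp4 drug cost moves its ICER monotonically upward
  dc <- tor[tor$path == "strategies.dpp4.annual_drug_cost", ]
  expect_lt(dc$icer_low, attr(tor, "base_icer"))
  expect_gt(dc$icer_high, attr(tor, "base_icer"))

  # a degenerate range produces zero spread
  same <- tibble::tibble(path = "unit_costs.gp_visit",
                         low = p$unit_costs$gp_visit,
                         high = p$unit_costs$gp_visit)
  expect_equal(tornado(p, "dpp4", "sulfonylurea", "65-79",
                       parameters = same)$spread, 0)

  expect_error(tornado(p, "dpp4", "sulfonylurea", "65-79",
                       parameters = tibble::tibble(path = "unit_costs.zzz",
                                                   low = 1, high = 2)),
               "unresolvable")
})

test_that("the default tornado sweep covers the bundle and is order-invariant", {
  p <- us_params()
  tor <- tornado(p, "dpp4", "sulfonylurea", "80plus")
  pt <- parameter_table(p)
  expect_equal(sort(tor$path), sort(pt$path))
  # defaulted ranges are +-25% (probabilities capped at 1)
  drug <- tor[tor$path == "strategies.dpp4.annual_drug_cost", ]
  expect_equal(drug$low, 0.75 * drug$base)
  expect_equal(drug$high, 1.25 * drug$base)
  amb <- tor[tor$path == "resource_use.p_ambulance", ]
  expect_equal(amb$high, 1)

  # listing order does not change results, only the final sort does
  sub <- tibble::tibble(
    path = c("unit_costs.hospitalization", "strategies.dpp4.annual_drug_cost"))
  sub$low <- purrr::map_dbl(sub$path, ~ 0.75 * hypocost:::get_param(p, .x))
  sub$high <- purrr::map_dbl(sub$path, ~ 1.25 * hypocost:::get_param(p, .x))
  t1 <- tornado(p, "dpp4", "sulfonylurea", "80plus", parameters = sub)
  t2 <- tornado(p, "dpp4", "sulfonylurea", "80plus", parameters = sub[2:1, ])
  expect_equal(as.data.frame(t1), as.data.frame(t2))
})

test_that("tidy, glance and autoplot work on sensitivity objects", {
  p <- us_params()
  psa <- run_psa(p, "65-79", psa_spec(30, seed = 3))
  expect_equal(nrow(tidy(psa)), 180)
  g <- glance(psa)
  expect_equal(g$n_iterations, 30)
  expect_equal(g$base_optimal, "metformin")
  cc <- ceac(psa)
  expect_s3_class(autoplot(cc), "ggplot")
  expect_s3_class(autoplot(psa), "ggplot")

  sub <- tibble::tibble(path = "strategies.dpp4.annual_drug_cost",
                        low = 1500, high = 2500)
  tor <- tornado(p, "dpp4", "sulfonylurea", "65-79", parameters = sub)
  expect_equal(tidy(tor)$base_icer[1], attr(tor, "base_icer"))
  expect_equal(glance(tor)$top_parameter, "strategies.dpp4.annual_drug_cost")
  expect_s3_class(autoplot(tor), "ggplot")
})
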