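#' Sensitivity analysis
#'
#' Two complementary analyses of parameter uncertainty. The one-way
#' deterministic analysis ([tornado()]) recomputes a pairwise ICER with each
#' scalar parameter moved to the ends of its range (default ±25% of the
#' base-case value) while all others stay at base. The probabilistic
#' analysis ([run_psa()]) draws every uncertain parameter jointly but
#' independently — gamma distributions for incidence base rates, costs and
#' per-event disutilities, a beta distribution for the base utility — and
#' re-evaluates the whole model per iteration; [ceac()] turns the resulting
#' cloud into cost-effectiveness acceptability curves. The ±25% range is
#' interpreted as a 95% interval half-width, so every sampled parameter has
#' standard deviation `range_fraction x mean / 1.96`.
#'
#' @name sensitivity
NULL

#' Probabilistic sensitivity analysis specification
#'
#' @param n_iterations Number of Monte-Carlo iterations (default 1000).
#' @param seed Integer seed making the draw sequence reproducible.
#' @param range_fraction Half-width of the 95% range as a fraction of the
#'   base value (default 0.25). `0` collapses every distribution to its
#'   mean, reproducing the base case exactly.
#' @return A list of class `hypocost_psa_spec`.
#' @export
psa_spec <- function(n_iterations = 1000, seed = NULL, range_fraction = 0.25) {
  stopifnot(n_iterations >= 1, range_fraction >= 0, range_fraction < 1)
  structure(list(n_iterations = as.integer(n_iterations), seed = seed,
                 range_fraction = range_fraction),
            class = "hypocost_psa_spec")
}

# the sampled parameter set: base rates, drug costs, unit costs and
# disutilities are gamma; the base utility is beta
psa_parameter_table <- function(params) {
  pt <- parameter_table(params, sections = c("strategies", "unit_costs", "utilities"))
  pt <- pt[grepl("\\.base_rate$|\\.annual_drug_cost$", pt$path) |
             grepl("^unit_costs\\.", pt$path) |
             grepl("^utilities\\.disutility\\.", pt$path) |
             pt$path == "utilities.u_base", ]
  pt$family <- ifelse(pt$path == "utilities.u_base", "beta", "gamma")
  pt
}

#' Draw parameter sets for the probabilistic sensitivity analysis
#'
#' Gamma draws are moment-matched so each parameter's mean equals its base
#' value and its standard deviation is `range_fraction x base / 1.96`; the
#' base utility is a moment-matched beta on (0, 1). Parameters with base
#' value zero cannot carry a gamma distribution and are held fixed with a
#' warning.
#'
#' @param params A `hypocost_params` bundle.
#' @param spec A [psa_spec()].
#' @return A tibble with `n_iterations` rows, one column per sampled
#'   parameter path plus `iteration`.
#' @export
#' @examples
#' draws <- sample_parameters(default_parameters("US"), psa_spec(10, seed = 1))
sample_parameters <- function(params, spec = psa_spec()) {
  stopifnot(inherits(spec, "hypocost_psa_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  pt <- psa_parameter_table(params)
  n <- spec$n_iterations
  rf <- spec$range_fraction

  fixed <- pt$family == "gamma" & pt$base <= 0
  if (any(fixed)) {
    warning("holding non-positive gamma parameters fixed: ",
            paste(pt$path[fixed], collapse = ", "), call. = FALSE)
  }
  draws <- purrr::map2(pt$base, seq_len(nrow(pt)), function(base, i) {
    if (rf == 0 || fixed[i]) return(rep(base, n))
    s <- rf * base / 1.96
    if (pt$family[i] == "gamma") {
      shape <- (base / s)^2          # = (1.96 / rf)^2
      stats::rgamma(n, shape = shape, rate = shape / base)
    } else {
      v <- s^2
      if (v >= base * (1 - base)) {
        stop("beta variance too large for mean ", base, call. = FALSE)
      }
      k <- base * (1 - base) / v - 1
      pmin(stats::rbeta(n, shape1 = base * k, shape2 = (1 - base) * k),
           1 - 1e-12)
    }
  })
  names(draws) <- pt$path
  dplyr::bind_cols(tibble::tibble(iteration = seq_len(n)),
                   tibble::as_tibble(draws, .name_repair = "minimal"))
}

#' Run the probabilistic sensitivity analysis
#'
#' Re-evaluates the full decision tree for every strategy under each sampled
#' parameter set, for one cohort. Risk multipliers depend only on the fixed
#' cohort profile; uncertainty in incidence enters through the sampled
#' medication base rates, exactly as the model's gamma family prescribes.
#'
#' @param params A `hypocost_params` bundle.
#' @param cohort Cohort label, `"65-79"` or `"80plus"`.
#' @param spec A [psa_spec()].
#' @param draws Optionally, a pre-computed draw table from
#'   [sample_parameters()] (otherwise drawn here).
#' @return An object of class `hypocost_psa` with elements `draws`
#'   (tibble: `iteration`, `strategy`, `cost`, `qaly`), `base` (the
#'   base-case outcomes for the cohort), `cohort`, `country`, `wtp` and
#'   `spec`. Supports [generics::tidy()], [generics::glance()] and
#'   [ggplot2::autoplot()].
#' @export
#' @examples
#' psa <- run_psa(default_parameters("US"), "65-79", psa_spec(100, seed = 7))
#' glance(psa)
run_psa <- function(params, cohort, spec = psa_spec(), draws = NULL) {
  stopifnot(cohort %in% names(params$cohorts))
  if (is.null(draws)) draws <- sample_parameters(params, spec)
  co <- params$cohorts[[cohort]]
  rc <- params$risk_constants
  mult <- risk_duration(co$diabetes_duration, rc) *
    risk_hba1c(co$hba1c, rc) * risk_bmi(co$bmi, rc) * risk_gfr(co$gfr, rc)

  g <- function(path) draws[[path]]  # sampled vector, length n_iterations
  sv <- params$severity
  ru <- params$resource_use
  br <- ru$severe_branches
  ut <- params$utilities

  mild_cost <- ru$p_hcp_contact *
    (g("unit_costs.gp_visit") +
       ru$p_assay_per_contact * g("unit_costs.blood_glucose_assay")) +
    ru$n_extra_smbg * (g("unit_costs.smbg_strip") + g("unit_costs.smbg_lancet"))
  moderate_cost <- mild_cost + ru$p_glucagon_moderate * g("unit_costs.glucagon_kit")
  transported <- br$er_only + br$hospitalization
  severe_cost <- br$gp * g("unit_costs.gp_visit") +
    br$np * g("unit_costs.np_visit") +
    br$outpatient * g("unit_costs.outpatient_visit") +
    br$er_only * g("unit_costs.er_visit") +
    br$hospitalization * g("unit_costs.hospitalization") +
    transported * (ru$p_ambulance * g("unit_costs.ambulance") +
                     ru$p_glucagon_severe * g("unit_costs.glucagon_kit")) +
    mild_cost
  d_mild <- ut$p_daytime_mild * g("utilities.disutility.mild_daytime") +
    (1 - ut$p_daytime_mild) * g("utilities.disutility.mild_nocturnal")
  d_modsev <- ut$p_daytime_modsev * g("utilities.disutility.modsev_daytime") +
    (1 - ut$p_daytime_modsev) * g("utilities.disutility.modsev_nocturnal")
  u_base <- g("utilities.u_base")

  out <- purrr::map_dfr(names(params$strategies), function(nm) {
    st <- params$strategies[[nm]]
    mild <- g(paste0("strategies.", nm, ".base_rate")) * mult
    moderate <- mild * sv$p_moderate / sv$p_mild
    severe <- mild * sv$p_severe / sv$p_mild
    hypo <- mild * mild_cost + moderate * moderate_cost + severe * severe_cost
    therapy <- g(paste0("strategies.", nm, ".annual_drug_cost")) +
      365 * st$daily_smbg_tests *
        (g("unit_costs.smbg_strip") + g("unit_costs.smbg_lancet")) +
      365 * st$daily_injections * g("unit_costs.needle") +
      g("unit_costs.home_monitor_annual")
    p_fatal <- fatality_prob(severe, ru)
    qaly <- pmax(u_base - mild * d_mild - (moderate + severe) * d_modsev -
                   p_fatal * ut$fatal_year_fraction_lost * u_base, 0)
    tibble::tibble(iteration = draws$iteration, strategy = nm,
                   cost = hypo + therapy, qaly = qaly)
  })

  base <- evaluate_strategies(params)
  structure(list(
    draws = out,
    base = base[base$cohort == cohort, ],
    cohort = cohort,
    country = params$country,
    wtp = params$settings$wtp_threshold,
    spec = spec
  ), class = "hypocost_psa")
}

#' @export
print.hypocost_psa <- function(x, ...) {
  cat("<hypocost_psa> ", x$country, ", cohort ", x$cohort, ": ",
      x$spec$n_iterations, " iterations x ",
      length(unique(x$draws$strategy)), " strategies\n", sep = "")
  invisible(x)
}

#' Cost-effectiveness acceptability curves
#'
#' At each willingness-to-pay value, the probability that each strategy is
#' cost-effective — i.e. maximizes net monetary benefit
#' (`qaly x wtp - cost`) among all strategies — across the PSA iterations.
#' Ties (which have probability zero under continuous draws) go to the
#' cheaper strategy. Probabilities sum to one at every grid point.
#'
#' @param psa A `hypocost_psa` object from [run_psa()].
#' @param wtp_grid Strictly increasing vector of willingness-to-pay values;
#'   defaults to 0 to twice the bundle's threshold in 41 steps.
#' @return A tibble of class `hypocost_ceac` with columns `wtp`, `strategy`,
#'   `probability`.
#' @export
ceac <- function(psa, wtp_grid = NULL) {
  stopifnot(inherits(psa, "hypocost_psa"))
  if (nrow(psa$draws) == 0) stop("empty PSA output", call. = FALSE)
  if (is.null(wtp_grid)) wtp_grid <- seq(0, 2 * psa$wtp, length.out = 41)
  if (any(diff(wtp_grid) <= 0)) {
    stop("wtp_grid must be strictly increasing", call. = FALSE)
  }
  strategies <- unique(psa$draws$strategy)
  cost <- matrix(psa$draws$cost, ncol = length(strategies))
  qaly <- matrix(psa$draws$qaly, ncol = length(strategies))
  colnames(cost) <- colnames(qaly) <- strategies

  res <- purrr::map_dfr(wtp_grid, function(w) {
    nmb <- qaly * w - cost
    # argmax by NMB, ties broken toward the cheaper strategy
    win <- apply(nmb - 1e-9 * cost / max(abs(cost)), 1, which.max)
    tab <- tabulate(win, nbins = length(strategies)) / nrow(nmb)
    tibble::tibble(wtp = w, strategy = strategies, probability = tab)
  })
  class(res) <- c("hypocost_ceac", class(res))
  attr(res, "country") <- psa$country
  attr(res, "cohort") <- psa$cohort
  res
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Recomputes the ICER of `strategy` versus `comparator` with each parameter
#' set to the low and high end of its range, all other parameters at base.
#' Ranges default to ±25% of the base value, with probabilities capped at 1.
#' Dominance at an endpoint is recorded as a signed infinity for sorting
#' (`-Inf` dominant, `+Inf` dominated) and labelled in the status columns.
#'
#' @param params A `hypocost_params` bundle.
#' @param strategy,comparator Strategy names to compare.
#' @param cohort Cohort label.
#' @param parameters Optionally a tibble with columns `path`, `low`, `high`;
#'   defaults to every scalar in the uncertain-parameter sections
#'   (see [parameter_table()]).
#' @param range_fraction Default range half-width as a fraction of base.
#'   Probabilities that are components of a categorical distribution (the
#'   severity split, the severe-event branches) are perturbed with their
#'   siblings renormalized proportionally, so every one-way scenario keeps a
#'   valid probability distribution.
#' @return A tibble of class `hypocost_dsa`, sorted by descending spread,
#'   with columns `path`, `base`, `low`, `high`, `icer_low`, `icer_high`,
#'   `status_low`, `status_high`, `spread`, and the base-case ICER as
#'   attribute `base_icer`. Supports [generics::tidy()] and
#'   [ggplot2::autoplot()].
#' @export
#' @examples
#' tornado(default_parameters("US"), "dpp4", "sulfonylurea", "65-79",
#'         parameters = tibble::tibble(path = "strategies.dpp4.annual_drug_cost",
#'                                     low = 1500, high = 2500))
tornado <- function(params, strategy, comparator, cohort,
                    parameters = NULL, range_fraction = 0.25) {
  stopifnot(strategy %in% names(params$strategies),
            comparator %in% names(params$strategies),
            cohort %in% names(params$cohorts))
  if (is.null(parameters)) {
    pt <- parameter_table(params)
    is_prob <- grepl("(^|\\.)p_", pt$path) | pt$path == "utilities.u_base" |
      grepl("fatal_year_fraction_lost", pt$path) |
      grepl("^severity\\.", pt$path) | grepl("severe_branches", pt$path)
    parameters <- tibble::tibble(
      path = pt$path,
      low = (1 - range_fraction) * pt$base,
      high = pmin((1 + range_fraction) * pt$base, ifelse(is_prob, 1, Inf))
    )
  }
  if (any(parameters$low > parameters$high)) {
    stop("each parameter range needs low <= high", call. = FALSE)
  }

  # components of a categorical distribution: perturbing one rescales the rest
  simplex_groups <- list(
    c("severity.p_mild", "severity.p_moderate", "severity.p_severe"),
    paste0("resource_use.severe_branches.", .severe_branch_names)
  )
  set_param_dsa <- function(p, path, value) {
    grp <- purrr::detect(simplex_groups, ~ path %in% .x)
    p <- set_param(p, path, value)
    if (!is.null(grp)) {
      others <- setdiff(grp, path)
      cur <- vapply(others, function(pp) get_param(p, pp), numeric(1))
      target <- 1 - value
      scaled <- if (sum(cur) > 0) cur * target / sum(cur)
                else rep(target / length(others), length(others))
      for (j in seq_along(others)) p <- set_param(p, others[j], scaled[j])
    }
    p
  }

  pair_icer <- function(p) {
    out <- evaluate_strategies(p)
    out <- out[out$cohort == cohort, ]
    icer(out[out$strategy == strategy, ], out[out$strategy == comparator, ])
  }
  as_value <- function(row) {
    switch(row$status,
           icer = if (row$southwest) -Inf else row$icer,
           dominant = -Inf,
           equivalent = 0,
           dominated = Inf)
  }

  base_row <- pair_icer(params)
  entries <- purrr::map_dfr(seq_len(nrow(parameters)), function(i) {
    path <- parameters$path[i]
    base <- get_param(params, path)
    if (is.null(base)) stop("unresolvable parameter path: ", path, call. = FALSE)
    lo <- pair_icer(set_param_dsa(params, path, parameters$low[i]))
    hi <- pair_icer(set_param_dsa(params, path, parameters$high[i]))
    vlo <- as_value(lo); vhi <- as_value(hi)
    # both ends at the same signed infinity means the status never moved
    spread <- if (vlo == vhi) 0 else abs(vhi - vlo)
    tibble::tibble(
      path = path, base = base,
      low = parameters$low[i], high = parameters$high[i],
      icer_low = vlo, icer_high = vhi,
      status_low = lo$status, status_high = hi$status,
      spread = spread
    )
  })
  entries <- entries[order(-entries$spread, entries$path), ]
  class(entries) <- c("hypocost_dsa", class(entries))
  attr(entries, "base_icer") <- as_value(base_row)
  attr(entries, "strategy") <- strategy
  attr(entries, "comparator") <- comparator
  attr(entries, "cohort") <- cohort
  attr(entries, "country") <- params$country
  entries
}
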