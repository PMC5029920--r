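#' Incremental cost-effectiveness analysis
#'
#' Pairwise comparison of strategies on the cost/QALY plane: incremental
#' cost per QALY gained (ICER), dominance classification (a strategy is
#' *dominant* if cheaper and more effective than its comparator, *dominated*
#' if costlier and less effective), and willingness-to-pay assessment.
#' Comparisons are pairwise against a single reference; no efficiency
#' frontier is constructed.
#'
#' @name cea
NULL

# absolute tolerance below which a delta counts as zero (machine-level tie)
.icer_tol <- 1e-9

#' Incremental cost-effectiveness of one strategy versus a comparator
#'
#' @param strategy_outcome,comparator_outcome Lists or one-row data frames
#'   with `annual_total_cost` and `qaly` (e.g. rows of
#'   [evaluate_strategies()] or [reference_outcomes()]). Both must share the
#'   same country and cohort when those fields are present.
#' @param wtp Willingness-to-pay threshold in currency per QALY, used to set
#'   `cost_effective`; `NA` leaves the flag `NA`.
#' @return A one-row tibble with `delta_cost`, `delta_qaly`, `status`
#'   (`"dominant"`, `"dominated"`, `"icer"` or `"equivalent"`), `icer`
#'   (numeric for status `"icer"`, `NA` otherwise), `southwest` (`TRUE` for
#'   a cheaper-but-less-effective ICER, which is not a value to rank by) and
#'   `cost_effective`.
#' @export
#' @examples
#' us <- evaluate_strategies(default_parameters("US"))
#' icer(us[us$strategy == "dpp4" & us$cohort == "65-79", ],
#'      us[us$strategy == "sulfonylurea" & us$cohort == "65-79", ],
#'      wtp = 54630)
icer <- function(strategy_outcome, comparator_outcome, wtp = NA_real_) {
  for (f in c("country", "cohort")) {
    a <- strategy_outcome[[f]]
    b <- comparator_outcome[[f]]
    if (!is.null(a) && !is.null(b) && !identical(a, b)) {
      stop("cannot compare outcomes across different `", f, "` values",
           call. = FALSE)
    }
  }
  dc <- strategy_outcome$annual_total_cost - comparator_outcome$annual_total_cost
  dq <- strategy_outcome$qaly - comparator_outcome$qaly
  zc <- abs(dc) <= .icer_tol
  zq <- abs(dq) <= .icer_tol

  if (zc && zq) {
    status <- "equivalent"; ratio <- NA_real_; sw <- FALSE
  } else if (dc <= .icer_tol && dq >= -.icer_tol) {
    status <- "dominant"; ratio <- NA_real_; sw <- FALSE
  } else if (dc >= -.icer_tol && dq <= .icer_tol) {
    status <- "dominated"; ratio <- NA_real_; sw <- FALSE
  } else {
    status <- "icer"; ratio <- dc / dq; sw <- dc < 0 && dq < 0
  }
  ce <- if (is.na(wtp)) NA else {
    status == "dominant" ||
      (status == "icer" && !sw && dq > 0 && ratio <= wtp)
  }
  tibble::tibble(
    delta_cost = dc, delta_qaly = dq, status = status,
    icer = ratio, southwest = sw, cost_effective = ce
  )
}

#' Compare all strategies against one reference
#'
#' One ICER row per non-reference strategy within each country and cohort
#' present in `outcomes`, ordered by decreasing cost-effectiveness
#' (dominant first, then rising ICERs, then southwest-quadrant entries,
#' then dominated).
#'
#' @param outcomes A tibble of strategy outcomes (columns `strategy`,
#'   `annual_total_cost`, `qaly`, optionally `cohort` and `country`), e.g.
#'   from [evaluate_strategies()] or [reference_outcomes()].
#' @param reference Name of the reference strategy (must appear in
#'   `outcomes`).
#' @param wtp Willingness-to-pay threshold: a single number, or a named
#'   vector keyed by country (e.g. `c(US = 54630, Canada = 53891)`), or `NA`.
#' @return A tibble of class `hypocost_cea`: one row per comparison with the
#'   columns of [icer()] plus `reference`, `strategy`, `cohort`, `country`.
#' @export
#' @examples
#' compare_strategies(reference_outcomes(), "sulfonylurea",
#'                    wtp = c(US = 54630, Canada = 53891))
compare_strategies <- function(outcomes, reference, wtp = NA_real_) {
  if (!reference %in% outcomes$strategy) {
    stop("unknown reference strategy: ", reference, call. = FALSE)
  }
  if (!"cohort" %in% names(outcomes)) outcomes$cohort <- "all"
  if (!"country" %in% names(outcomes)) outcomes$country <- "all"
  res <- outcomes |>
    dplyr::group_by(.data$country, .data$cohort) |>
    dplyr::group_modify(function(g, key) {
      ref <- g[g$strategy == reference, ]
      if (nrow(ref) != 1) {
        stop("reference strategy missing in cell ",
             paste(unlist(key), collapse = "/"), call. = FALSE)
      }
      w <- if (length(wtp) > 1 && !is.null(names(wtp))) {
        unname(wtp[[key$country]])
      } else {
        wtp
      }
      alt <- g[g$strategy != reference, ]
      purrr::map_dfr(seq_len(nrow(alt)), function(i) {
        dplyr::bind_cols(
          tibble::tibble(reference = reference, strategy = alt$strategy[i]),
          icer(alt[i, ], ref, wtp = w)
        )
      })
    }) |>
    dplyr::ungroup()
  # decreasing cost-effectiveness: dominant, rising ICERs, southwest, dominated
  key <- dplyr::case_when(
    res$status == "dominant" ~ -Inf,
    res$status == "equivalent" ~ 0,
    res$status == "icer" & !res$southwest ~ res$icer,
    res$status == "icer" & res$southwest ~ .Machine$double.xmax,
    res$status == "dominated" ~ Inf
  )
  res <- res[order(res$country, res$cohort, key), ]
  class(res) <- c("hypocost_cea", class(res))
  res
}

#' Convert an amount between currencies
#'
#' Plain multiplication by an exchange rate; the package never converts
#' silently — outputs carry the currency of their bundle.
#'
#' @param amount Amount in the source currency. Vectorized.
#' @param rate Units of target currency per unit of source currency (> 0).
#' @return `amount * rate`.
#' @export
#' @examples
#' convert_currency(50271, 1.0720)  # 53890.51 -> rounds to 53,891
convert_currency <- function(amount, rate) {
  if (any(rate <= 0)) fail_field("rate", "exchange rate must be positive")
  amount * rate
}

#' Published base-case reference outcomes
#'
#' Per-person annual total costs and QALYs for the six medication strategies
#' in both cohorts and countries, as printed in the published base-case
#' analysis this model re-implements. QALYs are country-invariant; the cost
#' columns reflect the original (unpublished) supplementary unit-cost
#' inputs, so they serve as an external benchmark for the cost-effectiveness
#' machinery rather than something the packaged synthetic unit costs
#' reproduce exactly.
#'
#' @return A tibble with 24 rows and columns `strategy`, `cohort`,
#'   `country`, `currency`, `annual_total_cost`, `qaly`.
#' @export
#' @examples
#' compare_strategies(reference_outcomes(), "metformin")
reference_outcomes <- function() {
  base <- tibble::tribble(
    ~strategy,       ~cohort,  ~cost_us, ~cost_can, ~qaly,
    "metformin",     "65-79",      433,      309,  0.831,
    "sulfonylurea",  "65-79",      709,      750,  0.805,
    "dpp4",          "65-79",     2307,     1228,  0.831,
    "tzd",           "65-79",      996,      835,  0.831,
    "glp1",          "65-79",     2332,     2942,  0.828,
    "basal_insulin", "65-79",     1522,     2206,  0.770,
    "metformin",     "80plus",     472,      356,  0.826,
    "sulfonylurea",  "80plus",     827,      892,  0.789,
    "dpp4",          "80plus",    2347,     1276,  0.826,
    "tzd",           "80plus",    1035,      883,  0.826,
    "glp1",          "80plus",    2381,     3002,  0.821,
    "basal_insulin", "80plus",    1788,     2528,  0.735
  )
  base |>
    tidyr::pivot_longer(c("cost_us", "cost_can"),
                        names_to = "country", values_to = "annual_total_cost") |>
    dplyr::mutate(
      country = ifelse(.data$country == "cost_us", "US", "Canada"),
      currency = ifelse(.data$country == "US", "2015 US$", "2015 CAN$")
    ) |>
    dplyr::select("strategy", "cohort", "country", "currency",
                  "annual_total_cost", "qaly")
}
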