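#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a probabilistic sensitivity analysis
#'
#' @param x A `hypocost_psa` object.
#' @param ... Unused.
#' @return The per-iteration draws: a tibble with `iteration`, `strategy`,
#'   `cost`, `qaly`.
#' @export
tidy.hypocost_psa <- function(x, ...) x$draws

#' One-row summary of a probabilistic sensitivity analysis
#'
#' @param x A `hypocost_psa` object.
#' @param ... Unused.
#' @return A tibble with the run's dimensions, the probability each draw's
#'   optimum lies with the base-case optimal strategy, and the seed.
#' @export
glance.hypocost_psa <- function(x, ...) {
  nmb <- x$draws$qaly * x$wtp - x$draws$cost
  by_iter <- tapply(nmb, x$draws$iteration, max)
  base_best <- x$base$strategy[which.max(x$base$qaly * x$wtp -
                                           x$base$annual_total_cost)]
  best <- x$draws |>
    dplyr::group_by(.data$iteration) |>
    dplyr::slice_max(.data$qaly * x$wtp - .data$cost, n = 1,
                     with_ties = FALSE) |>
    dplyr::ungroup()
  tibble::tibble(
    country = x$country,
    cohort = x$cohort,
    n_iterations = x$spec$n_iterations,
    n_strategies = length(unique(x$draws$strategy)),
    wtp = x$wtp,
    base_optimal = base_best,
    p_base_optimal = mean(best$strategy == base_best),
    mean_max_nmb = mean(by_iter),
    seed = x$spec$seed %||% NA_integer_
  )
}

#' Tidy a tornado analysis
#'
#' @param x A `hypocost_dsa` object.
#' @param ... Unused.
#' @return The entry table with the base-case ICER attached as a column.
#' @export
tidy.hypocost_dsa <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$base_icer <- attr(x, "base_icer")
  out
}

#' One-row summary of a tornado analysis
#'
#' @param x A `hypocost_dsa` object.
#' @param ... Unused.
#' @return A tibble naming the comparison, the base-case ICER and the most
#'   influential parameter.
#' @export
glance.hypocost_dsa <- function(x, ...) {
  tibble::tibble(
    strategy = attr(x, "strategy"),
    comparator = attr(x, "comparator"),
    cohort = attr(x, "cohort"),
    country = attr(x, "country"),
    base_icer = attr(x, "base_icer"),
    n_parameters = nrow(x),
    top_parameter = x$path[1],
    top_spread = x$spread[1]
  )
}

#' Tornado diagram
#'
#' Horizontal bars from the low-end to the high-end ICER for the most
#' influential parameters, with the base-case ICER as a vertical line.
#' Entries whose endpoints are dominance statuses (signed infinities) are
#' dropped from the drawing with a message; they remain in the table.
#'
#' @param object A `hypocost_dsa` object.
#' @param top Number of parameters to draw (default 15).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hypocost_dsa <- function(object, top = 15, ...) {
  dat <- tibble::as_tibble(object)
  finite <- is.finite(dat$icer_low) & is.finite(dat$icer_high)
  if (any(!finite)) {
    message(sum(!finite),
            " entries with dominance at an endpoint are not drawn")
  }
  dat <- dat[finite & dat$spread > 0, ]
  dat <- utils::head(dat, top)
  dat$path <- factor(dat$path, levels = rev(dat$path))
  ggplot2::ggplot(dat) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$icer_low, xend = .data$icer_high,
                   y = .data$path, yend = .data$path),
      linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = attr(object, "base_icer"),
                        linetype = "dashed") +
    ggplot2::labs(
      x = sprintf("ICER, %s vs %s (currency/QALY)",
                  attr(object, "strategy"), attr(object, "comparator")),
      y = NULL,
      title = sprintf("One-way sensitivity, %s cohort (%s)",
                      attr(object, "cohort"), attr(object, "country"))
    ) +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness acceptability curves
#'
#' @param object A `hypocost_ceac` tibble from [ceac()].
#' @param ... Unused.
#' @return A ggplot object: probability cost-effective versus
#'   willingness-to-pay, one curve per strategy.
#' @export
autoplot.hypocost_ceac <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$wtp, y = .data$probability,
                               colour = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = "Willingness to pay (currency/QALY)",
      y = "Probability cost-effective",
      colour = "Strategy",
      title = sprintf("Acceptability curves, %s cohort (%s)",
                      attr(object, "cohort"), attr(object, "country"))
    ) +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness plane of PSA draws
#'
#' @param object A `hypocost_psa` object.
#' @param ... Unused.
#' @return A ggplot object: one point per iteration and strategy on the
#'   (QALY, cost) plane, base-case outcomes overlaid.
#' @export
autoplot.hypocost_psa <- function(object, ...) {
  ggplot2::ggplot(object$draws,
                  ggplot2::aes(x = .data$qaly, y = .data$cost,
                               colour = .data$strategy)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.6) +
    ggplot2::geom_point(
      data = object$base,
      ggplot2::aes(x = .data$qaly, y = .data$annual_total_cost),
      colour = "black", shape = 4, size = 2) +
    ggplot2::labs(x = "QALYs/person-year", y = "Cost/person-year",
                  colour = "Strategy",
                  title = sprintf("PSA draws, %s cohort (%s)",
                                  object$cohort, object$country)) +
    ggplot2::theme_minimal()
}
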