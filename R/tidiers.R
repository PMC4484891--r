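#' Tidy a strategy-results table
#'
#' @param x A `cea_results` from [evaluate_strategies()].
#' @param ... Unused.
#' @return A plain tibble with `strategy`, `cost`, `qalys`.
#' @export
tidy.cea_results <- function(x, ...) as_tibble(x)

#' Summarise a strategy-results table
#'
#' @param x A `cea_results`.
#' @param ... Unused.
#' @return One-row tibble with the strategy count, cost range and QALY
#'   range.
#' @export
glance.cea_results <- function(x, ...) {
  tibble(
    n_strategies = nrow(x),
    min_cost = min(x$cost), max_cost = max(x$cost),
    min_qalys = min(x$qalys), max_qalys = max(x$qalys)
  )
}

#' Tidy a PSA result
#'
#' @param x A `cea_psa` from [run_psa()].
#' @param ... Unused.
#' @return Plain tibble of per-draw incremental results.
#' @export
tidy.cea_psa <- function(x, ...) as_tibble(x)

#' Summarise a PSA result
#'
#' Per-comparator means and the probability the reference strategy is
#' cost-effective at the configured willingness-to-pay threshold.
#'
#' @param x A `cea_psa`.
#' @param ... Unused.
#' @return Tibble with one row per comparator.
#' @export
glance.cea_psa <- function(x, ...) {
  wtp <- attr(x, "wtp_threshold") %||% 30000
  x |>
    group_by(.data$comparator) |>
    summarise(
      n_draws = dplyr::n(),
      mean_delta_cost = mean(.data$delta_cost),
      mean_delta_qaly = mean(.data$delta_qaly),
      prob_ce_at_wtp = mean(wtp * .data$delta_qaly - .data$delta_cost > 0),
      .groups = "drop"
    ) |>
    mutate(wtp_threshold = wtp)
}

#' Cost-effectiveness plane of a PSA result
#'
#' Scatter of incremental QALYs versus incremental costs per draw,
#' faceted by comparator, with the willingness-to-pay threshold line.
#'
#' @param object A `cea_psa`.
#' @param wtp Willingness-to-pay for the threshold line (euro/QALY).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cea_psa <- function(object, wtp = attr(object, "wtp_threshold") %||% 30000, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$delta_qaly, y = .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_abline(slope = wtp, intercept = 0, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
    ggplot2::facet_wrap(~comparator) +
    ggplot2::labs(
      x = "Incremental QALYs (reference - comparator)",
      y = "Incremental cost (€)",
      title = sprintf("Cost-effectiveness plane: %s vs comparators",
                      attr(object, "reference") %||% "reference")
    )
}

#' Plot cost-effectiveness acceptability curves
#'
#' @param object A `cea_ceac` from [ceac()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cea_ceac <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$wtp, y = .data$probability_ce, colour = .data$comparator
  )) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "Willingness to pay (€ per QALY)",
      y = "Probability reference is cost-effective",
      colour = "versus",
      title = "Cost-effectiveness acceptability curves"
    )
}

#' Plot a cohort trace
#'
#' State occupancy over time; states with negligible total occupancy are
#' dropped for legibility.
#'
#' @param object A `cea_trace` from [run_cohort()].
#' @param min_occupancy Drop states whose maximum occupancy stays below
#'   this value.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cea_trace <- function(object, min_occupancy = 0.01, ...) {
  keep <- object |>
    group_by(.data$state) |>
    summarise(peak = max(.data$occupancy), .groups = "drop") |>
    filter(.data$peak >= min_occupancy)
  ggplot2::ggplot(
    filter(object, .data$state %in% keep$state),
    ggplot2::aes(x = .data$time_years, y = .data$occupancy, colour = .data$state)
  ) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Time (years)", y = "Occupancy",
      title = sprintf("Cohort trace: %s", attr(object, "strategy") %||% "")
    )
}
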