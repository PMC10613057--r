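#' Tornado diagram of a one-way sensitivity analysis
#'
#' Horizontal bars spanning each parameter's low/high per-capita outputs,
#' ordered widest first, with the base value as a vertical reference line.
#'
#' @param object A `phc_tornado` from [one_way()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot phc_tornado
#' @export
autoplot.phc_tornado <- function(object, ...) {
  bars <- object$bars |>
    mutate(parameter = factor(.data$parameter,
                              levels = rev(.data$parameter)),
           lo = pmin(.data$low_output, .data$high_output),
           hi = pmax(.data$low_output, .data$high_output))
  ggplot2::ggplot(bars, ggplot2::aes(y = .data$parameter)) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$lo, xend = .data$hi, yend = .data$parameter),
      linewidth = 6, colour = "steelblue", lineend = "butt"
    ) +
    ggplot2::geom_vline(xintercept = object$base, linetype = "dashed") +
    ggplot2::labs(x = "Cost per capita (USD)", y = NULL,
                  title = "One-way sensitivity",
                  subtitle = sprintf("base %.2f; scenarios [%.2f, %.2f]",
                                     object$base, object$best_case,
                                     object$worst_case)) +
    ggplot2::theme_minimal()
}

#' @export
#' @rdname autoplot.phc_tornado
plot.phc_tornado <- function(x, ...) print(autoplot.phc_tornado(x, ...))

#' Stacked-bar chart of cost-category shares by facility level
#'
#' @param facilities Data frame of facilities, see [cost_category_shares()].
#' @return A ggplot object.
#' @export
plot_cost_shares <- function(facilities) {
  shares <- cost_category_shares(facilities)
  ggplot2::ggplot(shares,
                  ggplot2::aes(x = .data$level, y = .data$share,
                               fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x)) +
    ggplot2::labs(x = NULL, y = "Share of total cost", fill = NULL,
                  title = "Cost-category distribution by facility level") +
    ggplot2::theme_minimal()
}

#' Bar chart of actual vs normative per-capita costs
#'
#' @param gap A `phc_gap` tibble from [resource_gap()] with a `label`
#'   column.
#' @return A ggplot object.
#' @export
plot_gap <- function(gap) {
  stopifnot(inherits(gap, "phc_gap"))
  long <- gap |>
    as_tibble() |>
    tidyr::pivot_longer(c("actual_pc", "normative_pc"),
                        names_to = "kind", values_to = "per_capita") |>
    mutate(kind = dplyr::recode(.data$kind, actual_pc = "actual",
                                normative_pc = "normative"))
  x_aes <- if ("label" %in% names(long)) "label" else "kind"
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data[[x_aes]], y = .data$per_capita,
                               fill = .data$kind)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "Cost per capita (USD/person/year)",
                  fill = NULL,
                  title = "Actual vs normative PHC cost per capita") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
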