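#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Carbon balance component plot
#'
#' Stacked view of where substrate carbon ends up, as fractions of the
#' carbon fed; the gap to 1 is the unrecovered carbon.
#'
#' @param object A `balance_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.balance_report <- function(object, ...) {
  d <- tidy.balance_report(object)
  d$component <- factor(d$component, levels = rev(d$component))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$fraction, y = .data$component)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_x_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(
      x = "share of substrate carbon", y = NULL,
      title = paste0("Carbon balance: ", object$condition),
      subtitle = paste0("recovery ", round(object$carbon_recovery, 1), "%")
    ) +
    ggplot2::theme_minimal()
}

#' Specific flux bar plot
#'
#' @param object A `flux_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.flux_table <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d <- d[startsWith(d$unit, "mmol"), ]
  d$species <- stats::reorder(d$species, d$q)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$q, y = .data$species)) +
    ggplot2::geom_col(fill = "darkolivegreen4") +
    ggplot2::labs(x = "q (mmol / g cell N / h)", y = NULL,
                  title = "Specific production rates") +
    ggplot2::theme_minimal()
}

#' Pyrophosphate budget plot
#'
#' Anabolic supply and catabolic demand side by side, stacked by component,
#' visualising the supply shortfall.
#'
#' @param object A `ppi_budget`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ppi_budget <- function(object, ...) {
  d <- tidy.ppi_budget(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$side, y = .data$ppi,
                                  fill = .data$component)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "PPi (mmol / g cells)",
                  title = "Pyrophosphate supply vs demand") +
    ggplot2::theme_minimal()
}
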