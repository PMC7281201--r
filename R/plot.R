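## ggplot2 views of the result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a flux state
#'
#' Horizontal bar chart of the largest-magnitude fluxes (exchanges by
#' default carry the physiology: uptakes negative, secretion positive).
#'
#' @param object a `flux_state`.
#' @param top number of reactions shown.
#' @param categories reaction categories to include.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot flux_state
#' @export
autoplot.flux_state <- function(object, top = 20,
                                categories = c("exchange", "transport",
                                               "metabolic", "biomass",
                                               "maintenance"), ...) {
  df <- dplyr::filter(object$fluxes, .data$category %in% categories,
                      abs(.data$flux) > 0) |>
    dplyr::slice_max(abs(.data$flux), n = top)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$flux, y = stats::reorder(.data$reaction, abs(.data$flux)),
    fill = .data$subsystem)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "flux (mmol/gDCW/h)", y = NULL,
                  title = "Flux distribution") +
    ggplot2::theme_minimal()
}

#' Plot an essentiality report
#'
#' @param object an `essentiality_report`.
#' @param ... unused.
#' @return a ggplot of essential/non-essential counts per subsystem.
#' @method autoplot essentiality_report
#' @export
autoplot.essentiality_report <- function(object, ...) {
  df <- dplyr::count(object, .data$subsystem, .data$essential)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n, y = .data$subsystem,
                                   fill = .data$essential)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "reactions", y = NULL,
                  title = "Reaction essentiality by subsystem") +
    ggplot2::theme_minimal()
}

#' Pathway-distribution plot (total / active / essential per subsystem)
#'
#' @param summary output of [subsystem_summary()].
#' @return a ggplot.
#' @export
plot_subsystem_summary <- function(summary) {
  df <- tidyr::pivot_longer(summary, c("total", "active", "essential"),
                            names_to = "class", values_to = "n")
  df$class <- factor(df$class, levels = c("total", "active", "essential"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n, y = .data$subsystem,
                                   fill = .data$class)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "reactions", y = NULL,
                  title = "Total, active and essential reactions") +
    ggplot2::theme_minimal()
}

#' Plot a yield panel
#'
#' @param panel output of [yield_panel()].
#' @return a ggplot of yield (mol/mol CO2) per product, coloured by
#'   native/heterologous origin.
#' @export
plot_yield_panel <- function(panel) {
  df <- dplyr::filter(panel, !is.na(.data$yield))
  df$origin <- ifelse(df$heterologous, "heterologous", "native")
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$yield, y = stats::reorder(.data$product, .data$yield),
    fill = .data$origin)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "yield (mol product / mol CO2)", y = NULL,
                  title = "Maximum theoretical yields") +
    ggplot2::theme_minimal()
}

#' Plot a maintenance-energy sensitivity scan
#'
#' @param scan output of [energy_sensitivity_scan()].
#' @return a ggplot of photon uptake across the NGAM grid, one line per GAM.
#' @export
plot_sensitivity_scan <- function(scan) {
  df <- dplyr::filter(scan, .data$status == "optimal")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ngam, y = .data$photon_uptake,
                                   colour = factor(.data$gam))) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "NGAM (mmol ATP/gDCW/h)",
                  y = "photon uptake (mmol/gDCW/h)", colour = "GAM",
                  title = "Maintenance-energy sensitivity") +
    ggplot2::theme_minimal()
}
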