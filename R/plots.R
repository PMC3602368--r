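#' Plot a dispersal-threshold graph
#'
#' Draws the network in geographic space: edges as segments, sites as
#' points sized by habitat area and coloured by component.
#'
#' @param object A `dispersal_graph`.
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' ggplot2::autoplot(build_graph(worked_fixture(), 10))
#' @importFrom ggplot2 autoplot
#' @method autoplot dispersal_graph
#' @export
autoplot.dispersal_graph <- function(object, ...) {
  nodes <- graph_nodes(object)
  comp <- summarize_components(object)
  nodes <- dplyr::left_join(nodes, comp$membership, by = "site_id")
  edges <- graph_edges(object) |>
    dplyr::left_join(dplyr::select(nodes, source = "site_id",
                                   x = "x_km", y = "y_km"),
                     by = "source") |>
    dplyr::left_join(dplyr::select(nodes, target = "site_id",
                                   xend = "x_km", yend = "y_km"),
                     by = "target")
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$xend, yend = .data$yend),
      colour = "grey60", linewidth = 0.3) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x_km, y = .data$y_km,
                   size = .data$area_ha,
                   colour = factor(.data$component_id))) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (km)", y = "y (km)", colour = "component",
                  size = "area (ha)",
                  title = sprintf("%s network, threshold %g km",
                                  object$epoch, object$threshold)) +
    ggplot2::theme_minimal()
}

#' Plot a scenario comparison
#'
#' Current network with lost sites highlighted.
#'
#' @param object A `scenario_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot scenario_comparison
#' @export
autoplot.scenario_comparison <- function(object, ...) {
  nodes <- tidy(object) |>
    dplyr::left_join(dplyr::select(graph_nodes(object$current_graph),
                                   "site_id", "x_km", "y_km", "area_ha"),
                     by = "site_id")
  edges <- graph_edges(object$current_graph) |>
    dplyr::left_join(dplyr::select(nodes, source = "site_id",
                                   x = "x_km", y = "y_km"), by = "source") |>
    dplyr::left_join(dplyr::select(nodes, target = "site_id",
                                   xend = "x_km", yend = "y_km"),
                     by = "target")
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$xend, yend = .data$yend),
      colour = "grey70", linewidth = 0.3) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x_km, y = .data$y_km, size = .data$area_ha,
                   colour = .data$lost)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "#2166ac",
                                            `TRUE` = "#b2182b")) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (km)", y = "y (km)", colour = "lost",
                  size = "area (ha)") +
    ggplot2::theme_minimal()
}

#' Degree histogram with Poisson overlay
#'
#' @param x A [degree_distribution_summary()] result.
#' @return A ggplot object.
#' @export
plot_degree_distribution <- function(x) {
  hist <- x$histogram
  p <- ggplot2::ggplot(hist,
                       ggplot2::aes(x = .data$degree, y = .data$count)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::labs(x = "node degree", y = "count") +
    ggplot2::theme_minimal()
  if (!is.null(x$fit)) {
    expected <- tibble::tibble(
      degree = hist$degree,
      count = x$n * dpois(hist$degree, x$fit$lambda_hat))
    p <- p + ggplot2::geom_point(data = expected, colour = "#b2182b") +
      ggplot2::geom_line(data = expected, colour = "#b2182b",
                         linetype = "dashed")
  }
  p
}
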