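# ggplot2 autoplot methods for the result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot member growth rates
#'
#' @param object A `growth_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.growth_result <- function(object, ...) {
  assert_(object$status == "optimal", "nothing to plot: simulation not optimal")
  df <- object$member_growth
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$taxon_id, -.data$growth_rate),
                                   y = .data$growth_rate)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$abundance)) +
    ggplot2::geom_hline(yintercept = object$community_growth, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "growth rate (1/h)", fill = "abundance",
                  subtitle = paste0("community growth ",
                                    signif(object$community_growth, 4), " 1/h (dashed)")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a sensitivity report
#'
#' Correlation with the reference as a function of the abundance noise
#' level; the dashed line marks the noiseless baseline.
#'
#' @param object A `sensitivity_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sensitivity_report <- function(object, ...) {
  ggplot2::ggplot(object$results, ggplot2::aes(x = .data$noise_sd, y = .data$pearson_r)) +
    ggplot2::geom_hline(yintercept = object$baseline, linetype = "dashed") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "abundance noise sd (percent scale)",
                  y = "Pearson r vs reference",
                  subtitle = "dashed: noiseless baseline") +
    ggplot2::theme_minimal()
}

#' Plot an interaction graph
#'
#' Force-directed layout with edge colour encoding the interaction sign
#' (red competition / positive, green cooperation / negative, matching
#' the conventional knockout-network colouring).
#'
#' @param object An `interaction_graph`.
#' @param seed Layout seed.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.interaction_graph <- function(object, seed = 1, ...) {
  df <- tibble::as_tibble(object)
  assert_(nrow(df) > 0, "empty interaction graph")
  g <- igraph::graph_from_data_frame(df[, c("source", "target")], directed = TRUE)
  xy <- with_seed_(seed, igraph::layout_with_fr(g))
  nodes <- tibble::tibble(name = igraph::V(g)$name, x = xy[, 1], y = xy[, 2])
  df <- df |>
    dplyr::left_join(nodes, by = c(source = "name")) |>
    dplyr::left_join(nodes, by = c(target = "name"), suffix = c("", "_end"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = df,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$x_end, yend = .data$y_end,
                   colour = .data$sign, linewidth = abs(.data$weight)),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.15, "inches")), alpha = 0.8
    ) +
    ggplot2::geom_label(data = nodes, ggplot2::aes(x = .data$x, y = .data$y, label = .data$name)) +
    ggplot2::scale_colour_manual(values = c(positive = "#c0392b", negative = "#27ae60")) +
    ggplot2::scale_linewidth(range = c(0.3, 1.6), guide = "none") +
    ggplot2::theme_void() +
    ggplot2::labs(colour = "interaction")
}
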