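#' Plot a network
#'
#' Draws the graph with a seeded Fruchterman-Reingold layout: edge
#' colour encodes the sign of the partial correlation, edge width its
#' magnitude, node colour the variable dimension. Layout coordinates
#' are aesthetic only.
#'
#' @param object A `stratnet_graph`.
#' @param seed Layout seed.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stratnet_graph <- function(object, seed = 1L, ...) {
  g <- as_igraph(object)
  xy <- withr::with_seed(seed, igraph::layout_with_fr(
    g, weights = abs(igraph::E(g)$weight)))
  nodes <- object$nodes
  nodes$x <- xy[, 1]
  nodes$y <- xy[, 2]
  if (!"dimension" %in% names(nodes)) nodes$dimension <- "variable"
  edges <- object$edges |>
    dplyr::mutate(
      x = nodes$x[match(.data$from, nodes$name)],
      y = nodes$y[match(.data$from, nodes$name)],
      xend = nodes$x[match(.data$to, nodes$name)],
      yend = nodes$y[match(.data$to, nodes$name)],
      sign = ifelse(.data$weight >= 0, "positive", "negative")
    )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, colour = .data$sign,
                   linewidth = abs(.data$weight)),
      alpha = 0.7) +
    ggplot2::scale_colour_manual(
      values = c(positive = "#2166ac", negative = "#b2732d"),
      name = "edge sign") +
    ggplot2::scale_linewidth_continuous(range = c(0.2, 2), guide = "none") +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, fill = .data$dimension),
      shape = 21, size = 6) +
    ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$label),
      vjust = -1.2, size = 3) +
    ggplot2::scale_fill_manual(
      values = c(sociodemographic = "#66c2a5", personality = "#8da0cb",
                 psychopathology = "#fc8d62", variable = "grey70"),
      name = "dimension") +
    ggplot2::theme_void()
}

#' Centrality bar charts
#'
#' Nodes ordered by eigenvector centrality (relevance) and closeness
#' centrality (bridging capacity), one panel per measure.
#'
#' @param report A `stratnet_report` (or a centrality table from
#'   [centrality_table()]).
#' @return A ggplot object.
#' @export
plot_centrality <- function(report) {
  ct <- if (inherits(report, "stratnet_report")) report$centrality else report
  long <- ct |>
    dplyr::select("node", "eigenvector", "closeness") |>
    tidyr::pivot_longer(c("eigenvector", "closeness"),
                        names_to = "measure", values_to = "score")
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$score,
                               y = stats::reorder(.data$node, .data$score))) +
    ggplot2::geom_col(fill = "#4c72b0") +
    ggplot2::facet_wrap(~measure, scales = "free_x") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_centrality
#' @param object A `stratnet_report`.
#' @param ... Unused.
#' @export
autoplot.stratnet_report <- function(object, ...) plot_centrality(object)
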