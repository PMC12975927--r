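#' Full network report for one stratum
#'
#' Runs the complete per-stratum chain: partial-correlation estimation
#' with `p < alpha` edge retention, global metrics (edge count, density,
#' average path length, diameter), the centrality table, Louvain
#' community detection, and the activation view of the bridging node.
#' The node with the highest eigenvector centrality is reported as the
#' "most relevant" node; the node with the highest closeness (ties
#' broken by higher eigenvector, then node order) as the "bridging"
#' node.
#'
#' @param cohort A single-stratum `stratnet_cohort`.
#' @param stratum_label Text label for the stratum (e.g. `"FA+"`).
#' @param alpha Edge retention threshold.
#' @param seed Seed for community detection.
#' @param resolution Louvain resolution.
#' @return An object of class `stratnet_report`.
#' @export
network_report <- function(cohort, stratum_label, alpha = 0.25,
                           seed = 1L, resolution = 1) {
  graph <- estimate_stratum_network(cohort, alpha = alpha)
  n_v <- n_nodes(graph)
  paths <- if (n_edges(graph) > 0) {
    shortest_path_stats(graph)
  } else {
    tibble::tibble(avg_path_length = NA_real_, diameter = NA_real_)
  }
  centrality <- centrality_table(graph)
  communities <- louvain(graph, seed = seed, resolution = resolution)

  most_relevant <- centrality$node[which.max(centrality$eigenvector)]
  ord <- order(-centrality$closeness, -centrality$eigenvector,
               seq_len(nrow(centrality)))
  bridging <- centrality$node[ord[1]]

  structure(list(
    stratum_label = stratum_label,
    n = nrow(cohort),
    alpha = alpha,
    graph = graph,
    global_metrics = tibble::tibble(
      edge_count = n_edges(graph),
      density = graph_density(graph),
      avg_path_length = paths$avg_path_length,
      diameter = paths$diameter
    ),
    centrality = centrality,
    communities = communities,
    most_relevant = most_relevant,
    bridging = bridging,
    activation = activation_view(graph, bridging)
  ), class = "stratnet_report")
}

#' @export
print.stratnet_report <- function(x, ...) {
  g <- x$global_metrics
  cat("<stratnet report> stratum ", x$stratum_label, " (n = ", x$n, ")\n",
      "  edges: ", g$edge_count, "  density: ",
      format(round(g$density, 3), nsmall = 3),
      "  avg path length: ", format(round(g$avg_path_length, 3), nsmall = 3),
      "  diameter: ", g$diameter, "\n",
      "  communities: ", x$communities$n_communities,
      " (Q = ", format(round(x$communities$modularity, 3), nsmall = 3), ")\n",
      "  most relevant node: ", x$most_relevant,
      "   bridging node: ", x$bridging, "\n", sep = "")
  invisible(x)
}

#' @export
tidy.stratnet_report <- function(x, ...) {
  dplyr::left_join(x$centrality, tidy(x$communities), by = "node")
}

#' @export
glance.stratnet_report <- function(x, ...) {
  tibble::tibble(
    stratum_label = x$stratum_label, n = x$n,
    edge_count = x$global_metrics$edge_count,
    density = x$global_metrics$density,
    avg_path_length = x$global_metrics$avg_path_length,
    diameter = x$global_metrics$diameter,
    n_communities = x$communities$n_communities,
    modularity = x$communities$modularity,
    most_relevant = x$most_relevant, bridging = x$bridging
  )
}

report_to_list <- function(report) {
  list(
    stratum_label = report$stratum_label,
    n = report$n,
    alpha = report$alpha,
    nodes = as.list(report$graph$nodes),
    edges = as.list(report$graph$edges),
    global_metrics = as.list(report$global_metrics),
    centrality = as.list(report$centrality),
    communities = list(
      assignment = as.list(stats::setNames(
        as.integer(report$communities$assignment),
        names(report$communities$assignment))),
      n_communities = report$communities$n_communities,
      modularity = report$communities$modularity
    ),
    most_relevant = report$most_relevant,
    bridging = report$bridging,
    activation = as.list(report$activation)
  )
}

list_to_report <- function(x) {
  graph <- weighted_graph(tibble::as_tibble(x$nodes),
                          tibble::as_tibble(x$edges))
  assignment <- stats::setNames(as.integer(unlist(x$communities$assignment)),
                                names(x$communities$assignment))
  structure(list(
    stratum_label = x$stratum_label,
    n = x$n,
    alpha = x$alpha,
    graph = graph,
    global_metrics = tibble::as_tibble(x$global_metrics),
    centrality = tibble::as_tibble(x$centrality),
    communities = structure(list(
      assignment = assignment,
      n_communities = x$communities$n_communities,
      modularity = x$communities$modularity
    ), class = "stratnet_partition"),
    most_relevant = x$most_relevant,
    bridging = x$bridging,
    activation = tibble::as_tibble(x$activation)
  ), class = "stratnet_report")
}

#' Write one or more network reports to JSON
#'
#' Floats are serialized at full precision so that reading the file back
#' reproduces every metric bit-for-bit; a list of reports becomes a JSON
#' array.
#'
#' @param report A `stratnet_report` or a list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  payload <- if (inherits(report, "stratnet_report")) {
    report_to_list(report)
  } else {
    lapply(report, report_to_list)
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read reports written by [write_report()]
#'
#' @param path Input file path.
#' @return A `stratnet_report`, or a list of them if the file holds an
#'   array.
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  if (!is.null(x$stratum_label)) list_to_report(x) else lapply(x, list_to_report)
}
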