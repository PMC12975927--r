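#' Write a network to GEXF or GraphML
#'
#' Serializes the graph for standard network software (e.g. Gephi):
#' node metadata (label, dimension, mtype, plus any extra node columns
#' such as centralities or community ids) and signed edge weights with
#' their p-values are preserved, and reading the file back reconstructs
#' an identical graph. GEXF output follows the 1.2draft schema; GraphML
#' goes through igraph.
#'
#' @param graph A `stratnet_graph` with at least one node.
#' @param path Output file path.
#' @param format `"gexf"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_graph_file <- function(graph, path, format = c("gexf", "graphml")) {
  format <- match.arg(format)
  if (format == "gexf") {
    write_gexf(graph, path)
  } else {
    igraph::write_graph(as_igraph(graph), path, format = "graphml")
  }
  invisible(path)
}

#' Read a network written by [write_graph_file()]
#'
#' @param path Input file path.
#' @param format `"gexf"` or `"graphml"`; guessed from the file
#'   extension when omitted.
#' @return A `stratnet_graph`.
#' @export
read_graph_file <- function(path, format = NULL) {
  format <- format %||% switch(tolower(tools::file_ext(path)),
                               gexf = "gexf", graphml = "graphml",
                               stop("cannot guess format from extension; ",
                                    "pass format=", call. = FALSE))
  if (!format %in% c("gexf", "graphml")) {
    stop("unknown format: ", format, call. = FALSE)
  }
  if (format == "gexf") {
    read_gexf(path)
  } else {
    from_igraph(igraph::read_graph(path, format = "graphml"))
  }
}

from_igraph <- function(g) {
  nodes <- tibble::as_tibble(igraph::as_data_frame(g, what = "vertices"))
  edges <- tibble::as_tibble(igraph::as_data_frame(g, what = "edges"))
  names(nodes)[names(nodes) == "name"] <- "name"
  weighted_graph(nodes, edges)
}

# GEXF 1.2draft writer. Node attributes beyond the reserved label are
# declared in an attvalues block; edge weight uses the native GEXF
# weight attribute (signed), and the p-value rides as an edge attvalue.
write_gexf <- function(graph, path) {
  num17 <- function(x) {
    ifelse(is.na(x), "NA", vapply(x, function(v) {
      if (is.numeric(v)) sprintf("%.17g", v) else as.character(v)
    }, character(1)))
  }
  doc <- xml2::xml_new_root(
    "gexf", xmlns = "http://www.gexf.net/1.2draft", version = "1.2")
  gr <- xml2::xml_add_child(doc, "graph", defaultedgetype = "undirected")

  attr_cols <- setdiff(names(graph$nodes), c("name", "label"))
  if (length(attr_cols) > 0) {
    attrs <- xml2::xml_add_child(gr, "attributes", class = "node")
    for (i in seq_along(attr_cols)) {
      xml2::xml_add_child(attrs, "attribute", id = as.character(i - 1),
                          title = attr_cols[i],
                          type = if (is.numeric(graph$nodes[[attr_cols[i]]]))
                            "double" else "string")
    }
  }
  eattrs <- xml2::xml_add_child(gr, "attributes", class = "edge")
  xml2::xml_add_child(eattrs, "attribute", id = "p", title = "p",
                      type = "double")

  nodes_el <- xml2::xml_add_child(gr, "nodes")
  for (i in seq_len(nrow(graph$nodes))) {
    nd <- xml2::xml_add_child(nodes_el, "node",
                              id = graph$nodes$name[i],
                              label = graph$nodes$label[i])
    if (length(attr_cols) > 0) {
      av <- xml2::xml_add_child(nd, "attvalues")
      for (j in seq_along(attr_cols)) {
        xml2::xml_add_child(av, "attvalue", `for` = as.character(j - 1),
                            value = num17(graph$nodes[[attr_cols[j]]][i]))
      }
    }
  }
  edges_el <- xml2::xml_add_child(gr, "edges")
  for (i in seq_len(nrow(graph$edges))) {
    ed <- xml2::xml_add_child(edges_el, "edge", id = as.character(i - 1),
                              source = graph$edges$from[i],
                              target = graph$edges$to[i],
                              weight = num17(graph$edges$weight[i]))
    av <- xml2::xml_add_child(ed, "attvalues")
    xml2::xml_add_child(av, "attvalue", `for` = "p",
                        value = num17(graph$edges$p[i]))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

read_gexf <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)

  decl <- xml2::xml_find_all(doc, ".//attributes[@class='node']/attribute")
  attr_titles <- stats::setNames(xml2::xml_attr(decl, "title"),
                                 xml2::xml_attr(decl, "id"))
  attr_types <- stats::setNames(xml2::xml_attr(decl, "type"),
                                xml2::xml_attr(decl, "id"))

  node_els <- xml2::xml_find_all(doc, ".//nodes/node")
  nodes <- tibble::tibble(
    name = xml2::xml_attr(node_els, "id"),
    label = xml2::xml_attr(node_els, "label")
  )
  for (id in names(attr_titles)) {
    vals <- vapply(node_els, function(nd) {
      v <- xml2::xml_attr(
        xml2::xml_find_first(nd, paste0(".//attvalue[@for='", id, "']")),
        "value")
      if (is.na(v)) NA_character_ else v
    }, character(1))
    nodes[[attr_titles[[id]]]] <- if (attr_types[[id]] == "double") {
      suppressWarnings(as.numeric(ifelse(vals == "NA", NA, vals)))
    } else {
      vals
    }
  }

  edge_els <- xml2::xml_find_all(doc, ".//edges/edge")
  edges <- tibble::tibble(
    from = xml2::xml_attr(edge_els, "source"),
    to = xml2::xml_attr(edge_els, "target"),
    weight = as.numeric(xml2::xml_attr(edge_els, "weight")),
    p = vapply(edge_els, function(ed) {
      v <- xml2::xml_attr(
        xml2::xml_find_first(ed, ".//attvalue[@for='p']"), "value")
      if (is.na(v) || v == "NA") NA_real_ else as.numeric(v)
    }, double(1))
  )
  weighted_graph(nodes, edges)
}

#' Write an edge list CSV
#'
#' @param graph A `stratnet_graph`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  readr::write_csv(graph$edges, path)
  invisible(path)
}
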