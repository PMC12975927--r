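#' Construct an undirected signed-weight graph
#'
#' The container used for every estimated network: an ordered node table
#' (carrying the variable metadata) and an edge table with signed
#' partial-correlation weights. Edges are stored once, with `from`
#' preceding `to` in node order; self-loops are rejected.
#'
#' @param nodes A data frame with at least a `name` column (unique); the
#'   columns `label`, `dimension` and `mtype` are carried along when
#'   present.
#' @param edges A data frame with columns `from`, `to`, `weight` and
#'   optionally `p`; `from`/`to` must name nodes.
#' @return An object of class `stratnet_graph`: a list with tibbles
#'   `nodes` and `edges`.
#' @export
weighted_graph <- function(nodes, edges = NULL) {
  nodes <- tibble::as_tibble(nodes)
  if (!"name" %in% names(nodes)) stop("nodes need a 'name' column", call. = FALSE)
  if (anyDuplicated(nodes$name)) stop("node names must be unique", call. = FALSE)
  if (nrow(nodes) < 1) stop("graph needs at least one node", call. = FALSE)
  if (!"label" %in% names(nodes)) nodes$label <- nodes$name

  if (is.null(edges) || nrow(edges) == 0) {
    edges <- tibble::tibble(from = character(), to = character(),
                            weight = double(), p = double())
  } else {
    edges <- tibble::as_tibble(edges)
    if (!all(c("from", "to", "weight") %in% names(edges))) {
      stop("edges need columns from, to, weight", call. = FALSE)
    }
    if (!"p" %in% names(edges)) edges$p <- NA_real_
    i <- match(edges$from, nodes$name)
    j <- match(edges$to, nodes$name)
    if (anyNA(i) || anyNA(j)) stop("edge endpoint not in node table", call. = FALSE)
    if (any(i == j)) stop("self-loops are not allowed", call. = FALSE)
    swap <- i > j
    tmp <- edges$from[swap]
    edges$from[swap] <- edges$to[swap]
    edges$to[swap] <- tmp
    key <- paste(edges$from, edges$to)
    if (anyDuplicated(key)) stop("duplicate edges", call. = FALSE)
    edges <- edges[order(match(edges$from, nodes$name),
                         match(edges$to, nodes$name)),
                   c("from", "to", "weight", "p")]
  }
  structure(list(nodes = nodes, edges = edges), class = "stratnet_graph")
}

n_nodes <- function(graph) nrow(graph$nodes)
n_edges <- function(graph) nrow(graph$edges)

#' Adjacency matrix of a graph
#'
#' @param graph A `stratnet_graph`.
#' @param absolute Use absolute edge weights.
#' @param binary Use 0/1 adjacency (unweighted topology).
#' @return A symmetric numeric matrix in node order.
#' @export
adjacency_matrix <- function(graph, absolute = FALSE, binary = FALSE) {
  n <- n_nodes(graph)
  A <- matrix(0, n, n, dimnames = list(graph$nodes$name, graph$nodes$name))
  if (n_edges(graph) > 0) {
    i <- match(graph$edges$from, graph$nodes$name)
    j <- match(graph$edges$to, graph$nodes$name)
    w <- if (binary) 1 else graph$edges$weight
    if (absolute) w <- abs(w)
    A[cbind(i, j)] <- w
    A[cbind(j, i)] <- w
  }
  A
}

#' Graph density
#'
#' The number of retained edges divided by the number of potential edges
#' `n * (n - 1) / 2`; for the 17-node schema the denominator is 136.
#'
#' @param graph A `stratnet_graph` with at least two nodes.
#' @return A fraction in `[0, 1]`.
#' @export
graph_density <- function(graph) {
  n <- n_nodes(graph)
  if (n < 2) stop("density needs at least 2 nodes", call. = FALSE)
  n_edges(graph) / (n * (n - 1) / 2)
}

# BFS hop distances between all node pairs; Inf where unreachable.
hop_distances <- function(graph) {
  n <- n_nodes(graph)
  A <- adjacency_matrix(graph, binary = TRUE)
  D <- matrix(Inf, n, n, dimnames = dimnames(A))
  diag(D) <- 0
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    frontier <- s
    d <- 0
    while (length(frontier) > 0) {
      d <- d + 1
      nxt <- which(is.infinite(dist) & colSums(A[frontier, , drop = FALSE]) > 0)
      dist[nxt] <- d
      frontier <- nxt
    }
    D[s, ] <- dist
  }
  D
}

#' Average path length and diameter
#'
#' Distances are unweighted hop counts on the retained topology (edge
#' weights are similarities, not costs). The average is taken over all
#' ordered pairs of distinct, mutually reachable nodes; the diameter is
#' the largest finite distance.
#'
#' @param graph A `stratnet_graph` with at least two nodes and one edge.
#' @return A one-row tibble with `avg_path_length` and `diameter`.
#' @export
shortest_path_stats <- function(graph) {
  if (n_nodes(graph) < 2) stop("need at least 2 nodes", call. = FALSE)
  if (n_edges(graph) == 0) {
    stop("graph has no edges: no finite paths exist", call. = FALSE)
  }
  D <- hop_distances(graph)
  off <- D[row(D) != col(D)]
  finite <- off[is.finite(off)]
  tibble::tibble(avg_path_length = mean(finite), diameter = max(finite))
}

#' Eigenvector centrality (relevance)
#'
#' Power iteration on the absolute-weight adjacency matrix, scaled so the
#' maximum score is 1. A node's score is proportional to the weighted sum
#' of its neighbours' scores, so high values flag nodes connected to
#' other well-connected nodes ("relevance" in the clinical reading).
#'
#' @param graph A `stratnet_graph` with at least one edge.
#' @param tol Convergence tolerance on the maximum componentwise change.
#' @param max_iter Iteration cap.
#' @return A tibble with columns `node` and `eigenvector`.
#' @export
eigenvector_centrality <- function(graph, tol = 1e-8, max_iter = 1000L) {
  if (n_edges(graph) == 0) stop("eigenvector centrality needs >= 1 edge", call. = FALSE)
  A <- adjacency_matrix(graph, absolute = TRUE)
  # small diagonal shift: leaves every eigenvector unchanged but breaks
  # the +/- eigenvalue symmetry of bipartite topologies that would make
  # plain power iteration oscillate
  shift <- 0.1 * max(rowSums(A))
  diag(A) <- diag(A) + shift
  x <- rep(1, n_nodes(graph))
  for (it in seq_len(max_iter)) {
    x_new <- as.vector(A %*% x)
    x_new <- x_new / max(x_new)
    delta <- max(abs(x_new - x))
    x <- x_new
    if (delta < tol) {
      return(tibble::tibble(node = graph$nodes$name, eigenvector = x))
    }
  }
  stop("power iteration did not converge in ", max_iter,
       " iterations (residual ", format(delta), ")", call. = FALSE)
}

#' Closeness centrality (bridging capacity)
#'
#' For node `v` reaching `n_r` other nodes with hop distances `d`,
#' closeness is `(n_r / sum(d)) * (n_r / (n - 1))`: the reciprocal of the
#' mean distance to reachable nodes, corrected by the reachable fraction
#' so that scores from different components are comparable. Isolated
#' nodes score 0. The maximizer is the network's "bridging node".
#'
#' @param graph A `stratnet_graph` with at least two nodes.
#' @return A tibble with columns `node` and `closeness`.
#' @export
closeness_centrality <- function(graph) {
  n <- n_nodes(graph)
  if (n < 2) stop("need at least 2 nodes", call. = FALSE)
  D <- hop_distances(graph)
  scores <- vapply(seq_len(n), function(v) {
    d <- D[v, -v]
    reach <- is.finite(d) & d > 0
    n_r <- sum(reach)
    if (n_r == 0) return(0)
    (n_r / sum(d[reach])) * (n_r / (n - 1))
  }, double(1))
  tibble::tibble(node = graph$nodes$name, closeness = scores)
}

#' Local clustering coefficients
#'
#' For a node of degree >= 2, the fraction of its neighbour pairs that are
#' themselves connected, on the unweighted topology; nodes of degree < 2
#' score 0. The average is taken over nodes of degree >= 2.
#'
#' @param graph A `stratnet_graph` with at least three nodes.
#' @return A tibble with columns `node`, `degree` and `clustering`; the
#'   average over nodes of degree >= 2 is attached as attribute
#'   `"average"` (NA if no such node).
#' @export
clustering_coefficients <- function(graph) {
  if (n_nodes(graph) < 3) stop("need at least 3 nodes", call. = FALSE)
  A <- adjacency_matrix(graph, binary = TRUE)
  deg <- rowSums(A)
  cc <- vapply(seq_len(nrow(A)), function(v) {
    if (deg[v] < 2) return(0)
    nb <- which(A[v, ] > 0)
    links <- sum(A[nb, nb]) / 2
    2 * links / (deg[v] * (deg[v] - 1))
  }, double(1))
  out <- tibble::tibble(node = graph$nodes$name, degree = as.integer(deg),
                        clustering = cc)
  attr(out, "average") <- if (any(deg >= 2)) mean(cc[deg >= 2]) else NA_real_
  out
}

#' Node centrality table
#'
#' Eigenvector, closeness and clustering coefficients for every node,
#' with dense ranks per measure (1 = highest; ties broken by node order).
#'
#' @param graph A `stratnet_graph`.
#' @return A tibble with one row per node.
#' @export
centrality_table <- function(graph) {
  eig <- if (n_edges(graph) > 0) {
    eigenvector_centrality(graph)
  } else {
    tibble::tibble(node = graph$nodes$name, eigenvector = 0)
  }
  out <- eig |>
    dplyr::left_join(closeness_centrality(graph), by = "node") |>
    dplyr::left_join(clustering_coefficients(graph)[c("node", "clustering")],
                     by = "node")
  rank_stable <- function(x) {
    ord <- order(-x, seq_along(x))
    rk <- integer(length(x))
    rk[ord] <- seq_along(x)
    rk
  }
  out$rank_eigenvector <- rank_stable(out$eigenvector)
  out$rank_closeness <- rank_stable(out$closeness)
  out
}

#' Activation view of a node
#'
#' Splits the remaining nodes into those adjacent to the selected node
#' ("activated", reported with the signed edge weight and sorted by
#' decreasing absolute weight, ties by node order) and the non-adjacent
#' rest ("deactivated", in node order). This mirrors highlighting a
#' node's pattern of connections in a network viewer.
#'
#' @param graph A `stratnet_graph`.
#' @param node Name of the node to activate.
#' @return A tibble with columns `node`, `status` and `weight` (`NA` for
#'   deactivated nodes).
#' @export
activation_view <- function(graph, node) {
  if (!node %in% graph$nodes$name) {
    stop("unknown node: ", node, call. = FALSE)
  }
  e <- graph$edges
  inc <- e[e$from == node | e$to == node, ]
  other <- as.character(ifelse(inc$from == node, inc$to, inc$from))
  act <- tibble::tibble(node = other, status = rep("activated", length(other)),
                        weight = inc$weight)
  act <- act[order(-abs(act$weight), match(act$node, graph$nodes$name)), ]
  rest <- setdiff(graph$nodes$name, c(node, other))
  deact <- tibble::tibble(node = rest[order(match(rest, graph$nodes$name))],
                          status = "deactivated", weight = NA_real_)
  dplyr::bind_rows(act, deact)
}

#' @export
print.stratnet_graph <- function(x, ...) {
  cat("<stratnet graph> ", n_nodes(x), " nodes, ", n_edges(x),
      " edges (density ", format(round(graph_density(x), 3), nsmall = 3),
      ")\n", sep = "")
  invisible(x)
}

#' @export
tidy.stratnet_graph <- function(x, ...) x$edges

# Convert to an igraph object (used for layout and GraphML I/O).
as_igraph <- function(graph) {
  g <- igraph::graph_from_data_frame(
    d = as.data.frame(graph$edges),
    directed = FALSE,
    vertices = as.data.frame(graph$nodes)
  )
  g
}
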