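#' Weighted modularity of a partition
#'
#' Newman-Girvan modularity on absolute edge weights:
#' `Q = (1/2m) * sum_ij (A_ij - gamma * k_i k_j / (2m)) * delta(c_i, c_j)`
#' with `m` the total weight, `k` the node strengths and `gamma` the
#' resolution. Signed network variants of Q are nonstandard; magnitudes
#' are used, matching common network-viewer implementations.
#'
#' @param graph A `stratnet_graph` with positive total weight.
#' @param assignment Community membership: a vector (named by node or in
#'   node order) of community ids.
#' @param resolution Resolution parameter `gamma`, default 1.
#' @return The modularity Q.
#' @export
modularity_q <- function(graph, assignment, resolution = 1) {
  A <- adjacency_matrix(graph, absolute = TRUE)
  m2 <- sum(A)
  if (m2 == 0) stop("graph has zero total weight", call. = FALSE)
  memb <- membership_vector(graph, assignment)
  k <- rowSums(A)
  same <- outer(memb, memb, "==")
  sum((A - resolution * tcrossprod(k) / m2) * same) / m2
}

membership_vector <- function(graph, assignment) {
  if (!is.null(names(assignment))) {
    if (!all(graph$nodes$name %in% names(assignment))) {
      stop("assignment must cover every node", call. = FALSE)
    }
    assignment <- assignment[graph$nodes$name]
  }
  if (length(assignment) != n_nodes(graph) || anyNA(assignment)) {
    stop("assignment must cover every node", call. = FALSE)
  }
  as.integer(factor(assignment))
}

#' Louvain community detection
#'
#' Two-phase modularity optimization on absolute edge weights: repeated
#' local moves (nodes visited in a seeded shuffled order; a node moves to
#' the first neighbouring community giving a strictly positive modularity
#' gain) until no move improves, then aggregation of communities into
#' super-nodes, iterated until modularity stops increasing. Requiring a
#' strictly positive gain prevents cycling; the seed makes run-to-run
#' variation explicit and reproducible. Community ids are relabelled by
#' decreasing size (ties by node order) and are 0-based.
#'
#' @param graph A `stratnet_graph` with at least one edge.
#' @param seed Integer seed for the node-order shuffles.
#' @param resolution Resolution parameter, default 1 (larger values give
#'   more, smaller communities).
#' @return An object of class `stratnet_partition`: a list with
#'   `assignment` (named integer vector, 0-based contiguous ids),
#'   `n_communities` and `modularity`.
#' @export
louvain <- function(graph, seed = 1L, resolution = 1) {
  if (n_edges(graph) == 0) stop("community detection needs >= 1 edge", call. = FALSE)
  A <- adjacency_matrix(graph, absolute = TRUE)
  n <- nrow(A)
  # membership of the original nodes in terms of current super-nodes
  node_comm <- seq_len(n)
  withr::with_seed(seed, {
    repeat {
      memb <- louvain_one_level(A, resolution)
      node_comm <- memb[node_comm]
      n_comm <- max(memb)
      if (n_comm == nrow(A)) break
      # aggregate: A_agg[c, c] accumulates 2x internal weight so that
      # rowSums() remains the community strength
      S <- matrix(0, nrow(A), n_comm)
      S[cbind(seq_len(nrow(A)), memb)] <- 1
      A <- t(S) %*% A %*% S
      if (nrow(A) == 1) break
    }
  })
  ids <- relabel_by_size(node_comm)
  assignment <- stats::setNames(ids, graph$nodes$name)
  structure(list(
    assignment = assignment,
    n_communities = length(unique(ids)),
    modularity = modularity_agg_safe(graph, assignment, resolution)
  ), class = "stratnet_partition")
}

# One level of local moving on a (possibly aggregated, self-looped)
# absolute-weight adjacency matrix. Self-loop weight at A[i,i] counts
# twice toward strength, consistent with rowSums(). Returns a contiguous
# membership vector.
louvain_one_level <- function(A, resolution) {
  n <- nrow(A)
  memb <- seq_len(n)
  k <- rowSums(A)
  m2 <- sum(A)
  sigma_tot <- k[memb]
  improved <- TRUE
  while (improved) {
    improved <- FALSE
    for (i in sample.int(n)) {
      ci <- memb[i]
      nb <- which(A[i, ] > 0 & seq_len(n) != i)
      if (length(nb) == 0) next
      nb <- nb[sample.int(length(nb))]
      # weight from i into each candidate community
      w_to <- tapply(A[i, nb], memb[nb], sum)
      cand <- as.integer(names(w_to))
      w_own <- if (as.character(ci) %in% names(w_to)) w_to[[as.character(ci)]] else 0
      base <- w_own - resolution * (sigma_tot[ci] - k[i]) * k[i] / m2
      moved_to <- NA_integer_
      # first candidate (in shuffled neighbour order) with strict gain
      for (cc in unique(memb[nb])) {
        if (cc == ci) next
        gain <- (w_to[[as.character(cc)]] -
                   resolution * sigma_tot[cc] * k[i] / m2) - base
        if (gain > 1e-12) { moved_to <- cc; break }
      }
      if (!is.na(moved_to)) {
        sigma_tot[ci] <- sigma_tot[ci] - k[i]
        sigma_tot[moved_to] <- sigma_tot[moved_to] + k[i]
        memb[i] <- moved_to
        improved <- TRUE
      }
    }
  }
  as.integer(factor(memb))
}

relabel_by_size <- function(memb) {
  f <- factor(memb, levels = unique(memb))
  sizes <- table(f)
  ord <- order(-as.vector(sizes), seq_along(sizes))
  new_id <- integer(length(sizes))
  new_id[ord] <- seq_along(sizes) - 1L
  new_id[as.integer(f)]
}

modularity_agg_safe <- function(graph, assignment, resolution) {
  modularity_q(graph, assignment, resolution)
}

#' Summarise a community partition
#'
#' @param partition A `stratnet_partition`.
#' @param schema Optional schema supplying display labels.
#' @return A tibble with one row per community: `community`, `size` and
#'   `members` (comma-separated labels, in schema/node order), ordered by
#'   decreasing size.
#' @export
community_summary <- function(partition, schema = NULL) {
  nodes <- names(partition$assignment)
  labels <- if (!is.null(schema)) {
    schema$label[match(nodes, schema$name)]
  } else {
    nodes
  }
  tibble::tibble(node = nodes, label = labels,
                 community = as.integer(partition$assignment)) |>
    dplyr::group_by(.data$community) |>
    dplyr::summarise(size = dplyr::n(),
                     members = paste(.data$label, collapse = ", "),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$size), .data$community)
}

#' @export
print.stratnet_partition <- function(x, ...) {
  cat("<stratnet partition> ", x$n_communities, " communities, Q = ",
      format(round(x$modularity, 4), nsmall = 4), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.stratnet_partition <- function(x, ...) {
  tibble::tibble(node = names(x$assignment),
                 community = as.integer(x$assignment))
}

#' @export
glance.stratnet_partition <- function(x, ...) {
  tibble::tibble(n_communities = x$n_communities, modularity = x$modularity)
}
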