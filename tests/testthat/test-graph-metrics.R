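path_graph <- function(n) {
  nodes <- tibble::tibble(name = paste0("n", seq_len(n)))
  weighted_graph(nodes, tibble::tibble(from = nodes$name[-n],
                                       to = nodes$name[-1], weight = 1))
}

complete_graph <- function(n, weight = 1) {
  nodes <- tibble::tibble(name = paste0("n", seq_len(n)))
  idx <- which(upper.tri(diag(n)), arr.ind = TRUE)
  weighted_graph(nodes, tibble::tibble(from = nodes$name[idx[, 1]],
                                       to = nodes$name[idx[, 2]],
                                       weight = weight))
}

star_graph <- function(k) {
  nodes <- tibble::tibble(name = c("hub", paste0("leaf", seq_len(k))))
  weighted_graph(nodes, tibble::tibble(from = "hub",
                                       to = paste0("leaf", seq_len(k)),
                                       weight = 1))
}

cycle_graph <- function(n) {
  nodes <- tibble::tibble(name = paste0("n", seq_len(n)))
  weighted_graph(nodes, tibble::tibble(
    from = nodes$name, to = nodes$name[c(2:n, 1)], weight = 1))
}

test_that("density matches the potential-edge ratio", {
  g60 <- random_test_graph(17, seed = 1)
  g60$edges <- g60$edges[0, ]
  expect_equal(graph_density(g60), 0)
  expect_equal(round(60 / choose(17, 2), 3), 0.441)
  expect_equal(round(68 / choose(17, 2), 3), 0.5)
  expect_equal(graph_density(complete_graph(9)), 1)
})

test_that("path statistics match hand counts and the Floyd-Warshall oracle", {
  p4 <- shortest_path_stats(path_graph(4))
  expect_equal(p4$diameter, 3)
  expect_equal(p4$avg_path_length, 10 / 6)

  k17 <- shortest_path_stats(complete_graph(17))
  expect_equal(k17$diameter, 1)
  expect_equal(k17$avg_path_length, 1)

  for (seed in 1:20) {
    g <- random_test_graph(sample(5:20, 1), p_edge = stats::runif(1, 0.1, 0.6),
                           seed = seed)
    D <- floyd_warshall(g)
    st <- shortest_path_stats(g)
    off <- D[row(D) != col(D)]
    expect_equal(st$avg_path_length, mean(off[is.finite(off)]))
    expect_equal(st$diameter, max(off[is.finite(off)]))
  }
  g_empty <- weighted_graph(tibble::tibble(name = c("a", "b")))
  expect_error(shortest_path_stats(g_empty), "no edges")
})

test_that("eigenvector centrality has the symmetry and oracle properties", {
  st <- eigenvector_centrality(star_graph(4))
  expect_equal(st$eigenvector[st$node == "hub"], 1)
  leaves <- st$eigenvector[st$node != "hub"]
  expect_true(all(leaves < 1))
  expect_equal(stats::sd(leaves), 0)

  cyc <- eigenvector_centrality(cycle_graph(6))
  expect_equal(cyc$eigenvector, rep(1, 6))

  for (seed in 1:15) {
    g <- random_test_graph(sample(5:20, 1), p_edge = 0.5, seed = 100 + seed)
    est <- eigenvector_centrality(g)$eigenvector
    expect_equal(est, eigen_oracle(g), tolerance = 1e-6)
    # invariance to uniform weight scaling
    g2 <- g; g2$edges$weight <- g$edges$weight * 7.3
    expect_equal(eigenvector_centrality(g2)$eigenvector, est,
                 tolerance = 1e-6)
  }
})

test_that("closeness matches hand computation, the BFS oracle and the isolated-node rule", {
  p3 <- closeness_centrality(path_graph(3))
  expect_equal(p3$closeness, c(2 / 3, 1, 2 / 3))

  g <- star_graph(3)
  g$nodes <- dplyr::bind_rows(g$nodes, tibble::tibble(name = "iso", label = "iso"))
  cl <- closeness_centrality(g)
  expect_equal(cl$closeness[cl$node == "iso"], 0)

  for (seed in 1:15) {
    gr <- random_test_graph(sample(5:20, 1), p_edge = 0.25, seed = 200 + seed)
    expect_equal(closeness_centrality(gr)$closeness, closeness_oracle(gr))
  }
})

test_that("clustering coefficients match the triple-enumeration oracle", {
  tri <- complete_graph(3)
  expect_equal(clustering_coefficients(tri)$clustering, rep(1, 3))
  st <- clustering_coefficients(star_graph(5))
  expect_equal(st$clustering, rep(0, 6))
  expect_equal(attr(st, "average"), 0)

  for (seed in 1:15) {
    g <- random_test_graph(sample(5:20, 1), p_edge = 0.4, seed = 300 + seed)
    expect_equal(clustering_coefficients(g)$clustering, clustering_oracle(g))
  }
})

test_that("centralities agree on vertex-transitive graphs", {
  for (g in list(cycle_graph(7), complete_graph(6))) {
    ct <- centrality_table(g)
    expect_equal(stats::sd(ct$eigenvector), 0)
    expect_equal(stats::sd(ct$closeness), 0)
    expect_equal(stats::sd(ct$clustering), 0)
  }
})

test_that("adding an edge raises density and never lengthens paths", {
  for (seed in 1:10) {
    g <- random_test_graph(10, p_edge = 0.45, seed = 400 + seed)
    D <- floyd_warshall(g)
    if (any(is.infinite(D))) next
    A <- adjacency_matrix(g, binary = TRUE)
    free <- which(upper.tri(A) & A == 0, arr.ind = TRUE)
    if (nrow(free) == 0) next
    pick <- free[1, ]
    g2 <- g
    g2$edges <- dplyr::bind_rows(g2$edges, tibble::tibble(
      from = g$nodes$name[pick[1]], to = g$nodes$name[pick[2]],
      weight = 0.5, p = NA_real_))
    expect_gt(graph_density(g2), graph_density(g))
    expect_lte(shortest_path_stats(g2)$avg_path_length,
               shortest_path_stats(g)$avg_path_length)
  }
})

test_that("activation views partition the remaining nodes", {
  st <- star_graph(4)
  av <- activation_view(st, "hub")
  expect_true(all(av$status == "activated"))
  expect_equal(nrow(av), 4)

  g <- star_graph(3)
  g$nodes <- dplyr::bind_rows(g$nodes, tibble::tibble(name = "iso", label = "iso"))
  av_iso <- activation_view(g, "iso")
  expect_true(all(av_iso$status == "deactivated"))

  # a 17-node graph whose probe node has 11 of 16 possible edges
  nodes <- tibble::tibble(name = sprintf("v%02d", 1:17))
  edges <- tibble::tibble(from = "v01", to = sprintf("v%02d", 2:12),
                          weight = seq(0.9, -0.9, length.out = 11))
  g17 <- weighted_graph(nodes, edges)
  av17 <- activation_view(g17, "v01")
  expect_equal(sum(av17$status == "activated"), 11)
  expect_equal(sum(av17$status == "deactivated"), 5)
  act <- av17[av17$status == "activated", ]
  expect_true(all(diff(abs(act$weight)) <= 1e-12))

  expect_error(activation_view(g17, "nope"), "unknown node")
})
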