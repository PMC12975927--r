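# Independent brute-force oracles and fixture builders used across the
# suite. Everything here is deliberately naive (O(n^3) loops, dense
# eigendecompositions, exhaustive enumeration) and shares no code with
# the implementations it checks.

random_test_graph <- function(n, p_edge = 0.3, seed = 1, signed = TRUE,
                              ensure_edge = TRUE) {
  withr::with_seed(seed, {
    nodes <- tibble::tibble(name = sprintf("v%02d", seq_len(n)))
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    keep <- stats::runif(nrow(pairs)) < p_edge
    if (ensure_edge && !any(keep)) keep[sample.int(length(keep), 1)] <- TRUE
    w <- stats::runif(sum(keep), 0.05, 1)
    if (signed) w <- w * sample(c(-1, 1), length(w), replace = TRUE)
    edges <- tibble::tibble(from = nodes$name[pairs[keep, 1]],
                            to = nodes$name[pairs[keep, 2]],
                            weight = w)
    weighted_graph(nodes, edges)
  })
}

# All-pairs hop distances by Floyd-Warshall.
floyd_warshall <- function(graph) {
  A <- adjacency_matrix(graph, binary = TRUE)
  n <- nrow(A)
  D <- ifelse(A > 0, 1, Inf)
  diag(D) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  D
}

# Dominant eigenvector of the absolute-weight adjacency, max-normalized,
# from a full dense eigendecomposition.
eigen_oracle <- function(graph) {
  A <- adjacency_matrix(graph, absolute = TRUE)
  e <- eigen(A, symmetric = TRUE)
  v <- e$vectors[, which.max(e$values)]
  v <- abs(v)
  v / max(v)
}

# Closeness by per-source BFS over an edge list.
closeness_oracle <- function(graph) {
  D <- floyd_warshall(graph)
  n <- nrow(D)
  vapply(seq_len(n), function(v) {
    d <- D[v, -v]
    r <- is.finite(d)
    if (!any(r)) return(0)
    (sum(r) / sum(d[r])) * (sum(r) / (n - 1))
  }, double(1))
}

# Local clustering by explicit triple enumeration.
clustering_oracle <- function(graph) {
  A <- adjacency_matrix(graph, binary = TRUE)
  n <- nrow(A)
  vapply(seq_len(n), function(v) {
    nb <- which(A[v, ] > 0)
    if (length(nb) < 2) return(0)
    tri <- 0
    pairs <- utils::combn(nb, 2)
    for (c in seq_len(ncol(pairs))) {
      if (A[pairs[1, c], pairs[2, c]] > 0) tri <- tri + 1
    }
    tri / ncol(pairs)
  }, double(1))
}

# Modularity by the direct double sum over all ordered node pairs.
modularity_oracle <- function(graph, memb, resolution = 1) {
  A <- adjacency_matrix(graph, absolute = TRUE)
  k <- rowSums(A)
  m2 <- sum(A)
  q <- 0
  n <- nrow(A)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (memb[i] == memb[j]) {
        q <- q + A[i, j] - resolution * k[i] * k[j] / m2
      }
    }
  }
  unname(q / m2)
}

# All set partitions of 1..n as membership vectors (restricted growth
# strings); Bell(8) = 4140.
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxc) {
    i <- length(prefix) + 1
    if (i > n) {
      out[[length(out) + 1]] <<- prefix
      return()
    }
    for (c in seq_len(maxc + 1)) {
      rec(c(prefix, c), max(maxc, c))
    }
  }
  rec(integer(0), 0L)
  out
}

exhaustive_best_modularity <- function(graph) {
  parts <- all_partitions(nrow(graph$nodes))
  max(vapply(parts, function(p) modularity_oracle(graph, p), double(1)))
}

# Partial correlation of each pair given all other columns, via the
# correlation of residuals from two separate least-squares regressions.
pcorr_residual_oracle <- function(X) {
  X <- as.matrix(X)
  p <- ncol(X)
  out <- diag(1, p)
  dimnames(out) <- list(colnames(X), colnames(X))
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      ctrl <- cbind(1, X[, -c(i, j), drop = FALSE])
      ri <- stats::lm.fit(ctrl, X[, i])$residuals
      rj <- stats::lm.fit(ctrl, X[, j])$residuals
      out[i, j] <- out[j, i] <- stats::cor(ri, rj)
    }
  }
  out
}

# A data matrix whose *sample* correlation matrix equals `target`
# exactly: whiten an arbitrary draw empirically, then colour by the
# Cholesky factor of the target.
exact_correlation_data <- function(n, target, seed = 1) {
  p <- ncol(target)
  Z <- withr::with_seed(seed, matrix(stats::rnorm(n * p), n, p))
  Z <- scale(Z, center = TRUE, scale = FALSE)
  S <- crossprod(Z) / (n - 1)
  W <- Z %*% solve(chol(S))
  X <- W %*% chol(target)
  colnames(X) <- colnames(target) %||% paste0("x", seq_len(p))
  X
}

make_toy_cohort <- function(n_positive = 30, n_negative = 40, seed = 1) {
  generate_cohort(null_design(n_positive = n_positive,
                              n_negative = n_negative), seed = seed)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
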