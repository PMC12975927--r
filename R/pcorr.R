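#' Full partial-correlation matrix of a cohort
#'
#' Computes, for every pair of schema variables, the partial correlation
#' conditioning on all the remaining variables, by inverting the Pearson
#' correlation matrix: with precision `P = R^-1`,
#' `r_ij = -P_ij / sqrt(P_ii * P_jj)`. Binary variables enter as 0/1
#' indicators (point-biserial/phi special cases of Pearson). Two-sided
#' p-values come from `t = r * sqrt(df / (1 - r^2))` on `df = n - k - 2`
#' degrees of freedom, where `k` is the number of conditioned variables
#' (15 for the 17-node schema).
#'
#' @param data A single-stratum `stratnet_cohort` (the stratum column is
#'   dropped) or any numeric data frame / matrix of observations.
#' @param guard Condition-number threshold above which the correlation
#'   matrix is declared numerically singular.
#' @return An object of class `stratnet_pcorr`: a list with the matrices
#'   `r` and `p`, and scalars `n`, `k`, `df`; the schema travels along
#'   when the input was a cohort.
#' @export
partial_correlations <- function(data, guard = 1e10) {
  schema <- NULL
  if (inherits(data, "stratnet_cohort")) {
    schema <- cohort_schema(data)
    data <- tibble::as_tibble(data)[schema$name]
  }
  X <- as.matrix(data)
  storage.mode(X) <- "double"
  n <- nrow(X)
  p_vars <- ncol(X)
  if (p_vars < 2) stop("need at least 2 variables", call. = FALSE)
  if (n < 20) stop("need at least 20 observations per stratum", call. = FALSE)

  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant column(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "), call. = FALSE)
  }

  R <- stats::cor(X)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0 || max(ev) / min(ev) > guard) {
    P_try <- tryCatch(solve(R), error = function(e) NULL)
    vifs <- if (is.null(P_try)) rep(Inf, p_vars) else diag(P_try)
    worst <- colnames(X)[order(-vifs)][seq_len(min(3, p_vars))]
    stop("correlation matrix is numerically singular; ",
         "most collinear variables: ", paste(worst, collapse = ", "),
         call. = FALSE)
  }
  P <- solve(R)

  d <- sqrt(diag(P))
  r <- -P / tcrossprod(d)
  r <- (r + t(r)) / 2
  r[r > 1] <- 1
  r[r < -1] <- -1
  diag(r) <- 1

  k <- p_vars - 2
  df <- n - k - 2
  if (df <= 0) {
    stop("degrees of freedom n - k - 2 = ", df, " must be positive",
         call. = FALSE)
  }
  tval <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  pmat <- 2 * stats::pt(-abs(tval), df)
  diag(pmat) <- 0

  structure(list(r = r, p = pmat, n = n, k = k, df = df, schema = schema),
            class = "stratnet_pcorr")
}

#' Minimal |partial correlation| retained at a p-value threshold
#'
#' Inverts the two-sided t test: the absolute partial correlation at
#' which the p-value equals `alpha`, for sample size `n` and `k`
#' conditioned variables. Edges with `|r|` above this value are the ones
#' the `p < alpha` rule keeps.
#'
#' @param n Sample size.
#' @param k Number of conditioned variables (15 for the 17-node schema).
#' @param alpha Significance threshold, default 0.25.
#' @return The threshold on `|r|`.
#' @export
edge_p_threshold <- function(n, k, alpha = 0.25) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)", call. = FALSE)
  df <- n - k - 2
  if (df < 1) stop("n - k - 2 must be >= 1", call. = FALSE)
  tcrit <- stats::qt(1 - alpha / 2, df)
  tcrit / sqrt(df + tcrit^2)
}

#' Sparsify a partial-correlation result into a network
#'
#' Retains exactly the pairs whose two-sided p-value is strictly below
#' `alpha` (the liberal default 0.25 trades specificity for sensitivity:
#' absence of an edge is not evidence of a zero association, so weak
#' candidate edges are kept). All nodes remain in the graph even when
#' isolated; no multiple-testing correction is applied to edge p-values.
#'
#' @param pc A `stratnet_pcorr` object.
#' @param alpha Retention threshold on the edge p-value (strict `<`).
#' @param schema Optional schema to supply node metadata when `pc` was
#'   computed from a plain matrix.
#' @return A `stratnet_graph`.
#' @export
sparsify <- function(pc, alpha = 0.25, schema = NULL) {
  if (!(alpha > 0 && alpha <= 1)) stop("alpha must be in (0, 1]", call. = FALSE)
  vars <- colnames(pc$r)
  schema <- schema %||% pc$schema
  nodes <- if (!is.null(schema) && identical(schema$name, vars)) {
    schema[c("name", "label", "dimension", "mtype")]
  } else {
    tibble::tibble(name = vars, label = vars)
  }
  idx <- which(upper.tri(pc$r) & pc$p < alpha, arr.ind = TRUE)
  edges <- tibble::tibble(
    from = vars[idx[, 1]],
    to = vars[idx[, 2]],
    weight = pc$r[idx],
    p = pc$p[idx]
  )
  weighted_graph(nodes, edges)
}

#' Estimate the network of one stratum
#'
#' Composition of [partial_correlations()] and [sparsify()]: partial
#' correlations conditioned on all other nodes, thresholded at
#' `p < alpha`.
#'
#' @param cohort A single-stratum `stratnet_cohort`.
#' @param alpha Edge retention threshold, default 0.25.
#' @return A `stratnet_graph`.
#' @export
estimate_stratum_network <- function(cohort, alpha = 0.25) {
  sparsify(partial_correlations(cohort), alpha = alpha)
}

#' @export
print.stratnet_pcorr <- function(x, ...) {
  cat("<stratnet partial correlations> ", ncol(x$r), " variables, n = ",
      x$n, ", df = ", x$df, "\n", sep = "")
  invisible(x)
}

#' @export
tidy.stratnet_pcorr <- function(x, ...) {
  vars <- colnames(x$r)
  idx <- which(upper.tri(x$r), arr.ind = TRUE)
  tibble::tibble(
    var1 = vars[idx[, 1]],
    var2 = vars[idx[, 2]],
    estimate = x$r[idx],
    p_value = x$p[idx]
  )
}

#' @export
glance.stratnet_pcorr <- function(x, ...) {
  tibble::tibble(n = x$n, k = x$k, df = x$df, n_pairs = choose(ncol(x$r), 2))
}
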