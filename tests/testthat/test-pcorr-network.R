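test_that("partial correlations match closed forms in small systems", {
  # three variables with all pairwise correlations exactly 0.5 in the
  # sample: first-order recursion gives r_12|3 = (0.5 - 0.25)/(1 - 0.25)
  R <- matrix(0.5, 3, 3); diag(R) <- 1
  colnames(R) <- rownames(R) <- c("x", "y", "z")
  X <- exact_correlation_data(200, R, seed = 9)
  pc <- partial_correlations(X)
  expect_equal(pc$r["x", "y"], 1 / 3, tolerance = 1e-10)
  expect_equal(pc$k, 1)
  expect_equal(pc$df, 200 - 1 - 2)

  # with two variables (no controls) the partial correlation is Pearson
  X2 <- X[, 1:2]
  pc2 <- partial_correlations(X2)
  expect_equal(pc2$r[1, 2], stats::cor(X2)[1, 2], tolerance = 1e-12)
  expect_equal(pc2$k, 0)
})

test_that("precision-based estimates equal the regression-residual oracle", {
  for (seed in c(2, 3, 4)) {
    dat <- generate_cohort(default_design(), seed = seed)
    X <- tibble::as_tibble(dat)[attr(dat, "schema")$name]
    pc <- partial_correlations(dat |> (\(co) split_by_stratum(co)$negative)())
    Xn <- tibble::as_tibble(split_by_stratum(dat)$negative)[attr(dat, "schema")$name]
    oracle <- pcorr_residual_oracle(Xn)
    expect_equal(unname(pc$r), unname(oracle), tolerance = 1e-10)
  }
})

test_that("estimation guards its preconditions", {
  X <- matrix(stats::rnorm(100), 50, 2)
  X[, 2] <- 1
  expect_error(partial_correlations(X), "constant")
  withr::with_seed(1, {
    Y <- matrix(stats::rnorm(150), 50, 3)
  })
  colnames(Y) <- c("a", "b", "c")
  Y <- cbind(Y, d = Y[, "a"] + Y[, "b"])  # exact collinearity
  expect_error(partial_correlations(Y), "singular")
  expect_error(partial_correlations(matrix(stats::rnorm(30), 10, 3)),
               "at least 20")
})

test_that("p-values under the null are uniform", {
  nd <- null_design()
  pv <- unlist(lapply(1:74, function(r) {
    dat <- generate_cohort(nd, seed = 5000 + r)
    pc <- partial_correlations(split_by_stratum(dat)$negative)
    pc$p[upper.tri(pc$p)]
  }))
  expect_gte(length(pv), 1e4)
  ks <- suppressWarnings(stats::ks.test(pv, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("the retention threshold inverts the t test", {
  # numeric-inversion oracle: solve p(|r|) = alpha on (0, 1)
  p_of_r <- function(r, df) 2 * stats::pt(-abs(r) * sqrt(df / (1 - r^2)), df)
  for (case in list(c(78, 15, 0.25), c(131, 15, 0.25), c(78, 15, 0.05))) {
    thr <- edge_p_threshold(case[1], case[2], case[3])
    root <- stats::uniroot(function(r) p_of_r(r, case[1] - case[2] - 2) - case[3],
                           c(1e-8, 1 - 1e-8), tol = 1e-12)$root
    expect_equal(thr, root, tolerance = 1e-8)
  }
  expect_equal(edge_p_threshold(78, 15, 0.25), 0.147, tolerance = 0.001)
  expect_lt(edge_p_threshold(78, 15, 0.9999), 1e-3)
  expect_gt(edge_p_threshold(78, 15, 0.05), edge_p_threshold(78, 15, 0.25))
  expect_error(edge_p_threshold(78, 15, 1.5), "alpha")
  expect_error(edge_p_threshold(17, 15, 0.25), ">= 1")
})

test_that("sparsification keeps exactly the sub-threshold pairs", {
  dat <- split_by_stratum(generate_cohort(default_design(), seed = 6))$positive
  pc <- partial_correlations(dat)

  pc_all <- pc; pc_all$p[] <- 0; diag(pc_all$p) <- 0
  expect_equal(nrow(sparsify(pc_all)$edges), 136)
  pc_none <- pc; pc_none$p[] <- 1
  g0 <- sparsify(pc_none)
  expect_equal(nrow(g0$edges), 0)
  expect_equal(nrow(g0$nodes), 17)

  # boundary p exactly alpha is excluded (strict inequality)
  pc_b <- pc; pc_b$p[] <- 1
  pc_b$p[1, 2] <- pc_b$p[2, 1] <- 0.25
  pc_b$p[1, 3] <- pc_b$p[3, 1] <- 0.2499999
  expect_equal(nrow(sparsify(pc_b, 0.25)$edges), 1)

  # monotone in alpha and never above the complete-graph count
  g_lo <- sparsify(pc, 0.05); g_hi <- sparsify(pc, 0.25)
  key <- function(g) paste(g$edges$from, g$edges$to)
  expect_true(all(key(g_lo) %in% key(g_hi)))
  expect_lte(nrow(g_hi$edges), 136)
  # idempotence: re-thresholding the retained edges changes nothing
  expect_true(all(g_hi$edges$p < 0.25))
})

test_that("the stratum estimator is deterministic and tie-stable", {
  dat <- split_by_stratum(generate_cohort(default_design(), seed = 8))$positive
  g1 <- estimate_stratum_network(dat)
  g2 <- estimate_stratum_network(dat)
  expect_identical(g1$edges, g2$edges)

  # duplicating every row preserves the correlation structure exactly,
  # so the same edges are retained more strongly (df doubles)
  dat2 <- as_cohort(dplyr::bind_rows(tibble::as_tibble(dat),
                                     tibble::as_tibble(dat)))
  g3 <- estimate_stratum_network(dat2)
  key <- function(g) paste(g$edges$from, g$edges$to)
  expect_true(all(key(g1) %in% key(g3)))
})

test_that("under a null design the retention rate sits near alpha", {
  nd <- null_design()
  rates <- vapply(1:40, function(r) {
    pc <- partial_correlations(split_by_stratum(
      generate_cohort(nd, seed = 900 + r))$negative)
    mean(pc$p[upper.tri(pc$p)] < 0.25)
  }, double(1))
  expect_lt(abs(mean(rates) - 0.25), 3 * stats::sd(rates) / sqrt(40) + 0.01)
})
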