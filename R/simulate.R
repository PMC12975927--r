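#' Partial correlations implied by a precision matrix
#'
#' The planted ground truth of a simulation design: for a symmetric
#' positive-definite precision matrix `P`, the partial correlation of a
#' pair given all other variables is `-P_ij / sqrt(P_ii * P_jj)`; the
#' diagonal is reported as 1 by convention. Zeros in the precision are
#' exact conditional independences, so the support of this matrix is the
#' planted edge set.
#'
#' @param precision A symmetric positive-definite matrix.
#' @return A symmetric matrix of partial correlations with unit diagonal.
#' @export
planted_pcorr <- function(precision) {
  precision <- as.matrix(precision)
  if (!isSymmetric(precision, tol = 1e-10)) {
    stop("precision matrix must be symmetric", call. = FALSE)
  }
  ev <- eigen((precision + t(precision)) / 2, symmetric = TRUE,
              only.values = TRUE)$values
  if (min(ev) <= 0) stop("precision matrix must be positive-definite", call. = FALSE)
  d <- sqrt(diag(precision))
  pc <- -precision / tcrossprod(d)
  diag(pc) <- 1
  pc
}

# Build a unit-diagonal precision matrix whose implied partial
# correlations equal the target matrix exactly (P_ij = -T_ij, P_ii = 1),
# shrinking the weaker targets if needed until the smallest eigenvalue
# clears `min_eig`. Entries at or above `preserve` in magnitude are kept
# intact first; if that alone cannot reach positive-definiteness, all
# entries shrink.
precision_from_targets <- function(targets, min_eig = 0.05, preserve = 0.29) {
  P <- -as.matrix(targets)
  diag(P) <- 1
  soft <- abs(targets) < preserve & row(P) != col(P)
  for (iter in 1:200) {
    ev <- min(eigen(P, symmetric = TRUE, only.values = TRUE)$values)
    if (ev >= min_eig) return(P)
    if (iter <= 100 && any(soft & P != 0)) {
      P[soft] <- P[soft] * 0.95
    } else {
      off <- row(P) != col(P)
      P[off] <- P[off] * 0.95
    }
  }
  stop("could not reach positive-definiteness", call. = FALSE)
}

# Target partial-correlation matrices of the two default planted
# structures. Each stratum gets a distinct sparse support: the positive
# stratum a hub on self-directedness, the negative stratum a hub on
# self-transcendence; a few strong (|r| >= 0.3) edges among continuous
# non-ordinal variables; and weak filler edges drawn once from a fixed
# internal stream to reach ~60 (positive) and ~68 (negative) edges.
default_targets <- function(stratum, schema = default_schema()) {
  vars <- schema$name
  T <- matrix(0, 17, 17, dimnames = list(vars, vars))
  set_edge <- function(a, b, w) {
    T[a, b] <<- w
    T[b, a] <<- w
  }
  if (stratum == "positive") {
    hub <- "TCI.directed"
    hub_to <- c(Age = 0.16, SES = -0.12, Emotion = -0.14,
                Psy.Distress = -0.18, MentalDis = -0.14,
                TCI.novelty = -0.12, TCI.harm = -0.30, TCI.reward = 0.12,
                TCI.persis = 0.14, TCI.coopera = 0.18, TCI.transcen = 0.12)
    strong <- list(c("Impulsivity", "Emotion", 0.30),
                   c("Emotion", "Psy.Distress", 0.32),
                   c("TCI.novelty", "Impulsivity", 0.30))
    n_target <- 60
    fill_seed <- 104729
  } else {
    hub <- "TCI.transcen"
    hub_to <- c(Age = 0.12, Marit.NotMarr = -0.10, SES = -0.12,
                Impulsivity = -0.10, Psy.Distress = 0.12, MentalDis = 0.10,
                Suicidal = 0.10, DurationBA = 0.10, TCI.harm = 0.12,
                TCI.reward = 0.12, TCI.persis = 0.30, TCI.directed = -0.14,
                TCI.coopera = 0.14)
    strong <- list(c("TCI.harm", "Psy.Distress", 0.30),
                   c("TCI.reward", "TCI.coopera", 0.32),
                   c("Age", "DurationBA", 0.30))
    n_target <- 68
    fill_seed <- 224737
  }
  for (nm in names(hub_to)) set_edge(hub, nm, hub_to[[nm]])
  for (e in strong) set_edge(e[1], e[2], as.numeric(e[3]))

  used <- sum(T[upper.tri(T)] != 0)
  free <- which(upper.tri(T) & T == 0, arr.ind = TRUE)
  withr::with_seed(fill_seed, {
    pick <- free[sample.int(nrow(free), n_target - used), , drop = FALSE]
    w <- sample(c(-0.12, -0.10, 0.10, 0.12), nrow(pick), replace = TRUE)
  })
  for (r in seq_len(nrow(pick))) {
    set_edge(vars[pick[r, 1]], vars[pick[r, 2]], w[r])
  }
  T
}

default_var_scale <- function() {
  tibble::tribble(
    ~var,           ~mean, ~sd,
    "Age",           34.0, 15.5,
    "Impulsivity",  135.0, 22.0,
    "Emotion",       85.0, 22.0,
    "Psy.Distress",   1.1, 0.65,
    "DurationBA",     6.0, 2.5,
    "TCI.novelty",  105.0, 14.0,
    "TCI.harm",     102.0, 16.0,
    "TCI.reward",   100.0, 14.0,
    "TCI.persis",   112.0, 18.0,
    "TCI.directed", 128.0, 19.0,
    "TCI.coopera",  132.0, 15.0,
    "TCI.transcen",  63.0, 13.0
  )
}

#' Specify a synthetic-cohort simulation design
#'
#' Participants are latent multivariate Gaussian draws whose
#' conditional-dependence structure is set per stratum by a precision
#' matrix; the positive stratum additionally receives per-variable mean
#' shifts on the standardized (Cohen's d) scale. Binary variables are
#' produced by thresholding their latent coordinate at the cut point
#' that hits the stratum's target marginal proportion; downstream
#' estimation sees only the 0/1 values, deliberately reproducing the
#' attenuation a Pearson-based analysis of binary indicators incurs. The
#' social position index is discretized to its 5 ordered levels from
#' target marginal proportions.
#'
#' @param n_positive,n_negative Stratum sample sizes (defaults 78 and
#'   131).
#' @param schema Variable schema.
#' @param precision_positive,precision_negative Symmetric
#'   positive-definite latent precision matrices (schema order).
#' @param mean_shift Named vector of standardized mean differences
#'   (positive minus negative stratum) for continuous variables; binary
#'   entries must be 0 (their margins are set by `binary_targets`).
#' @param binary_targets Tibble with columns `var`, `p_positive`,
#'   `p_negative`: target marginal proportions of the level coded 1.
#' @param var_scale Tibble `var`, `mean`, `sd` mapping latent standard
#'   scores of continuous variables to reporting units.
#' @param ses_props Marginal proportions of the 5 ordered SES levels
#'   (codes 1 = high ... 5 = low).
#' @param seed Default integer seed for [generate_cohort()].
#' @return An object of class `stratnet_design`.
#' @export
simulation_design <- function(n_positive = 78L, n_negative = 131L,
                              schema = default_schema(),
                              precision_positive = NULL,
                              precision_negative = NULL,
                              mean_shift = NULL,
                              binary_targets = NULL,
                              var_scale = default_var_scale(),
                              ses_props = c(11, 34, 16, 53, 95) / 209,
                              seed = 1L) {
  schema <- variable_schema(schema)
  p <- nrow(schema)
  if (is.null(precision_positive)) {
    precision_positive <- precision_from_targets(default_targets("positive", schema))
  }
  if (is.null(precision_negative)) {
    precision_negative <- precision_from_targets(default_targets("negative", schema))
  }
  if (is.null(mean_shift)) {
    mean_shift <- stats::setNames(rep(0, p), schema$name)
    mean_shift[c("Age", "Impulsivity", "Emotion", "Psy.Distress",
                 "TCI.harm", "TCI.directed")] <-
      c(0.25, 0.45, 0.50, 0.55, 0.50, -0.60)
  }
  if (is.null(binary_targets)) {
    binary_targets <- tibble::tribble(
      ~var,            ~p_positive, ~p_negative,
      "Sex.Male",      0.513,       0.725,
      "Marit.NotMarr", 0.744,       0.748,
      "MentalDis",     0.450,       0.250,
      "Suicidal",      0.300,       0.150
    )
  }
  for (P in list(precision_positive, precision_negative)) {
    P <- as.matrix(P)
    if (!identical(dim(P), c(p, p)) && !identical(dim(P), as.integer(c(p, p)))) {
      stop("precision matrices must be ", p, " x ", p, call. = FALSE)
    }
    if (!isSymmetric(P, tol = 1e-10)) {
      stop("precision matrices must be symmetric", call. = FALSE)
    }
    if (min(eigen(P, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
      stop("precision matrices must be positive-definite", call. = FALSE)
    }
  }
  mean_shift <- mean_shift[schema$name]
  if (anyNA(mean_shift)) stop("mean_shift must cover every schema variable", call. = FALSE)
  if (any(abs(mean_shift) > 3)) stop("|mean_shift| must be <= 3", call. = FALSE)
  if (any(mean_shift[binary_vars(schema)] != 0)) {
    stop("mean_shift must be 0 for binary variables (margins are set by binary_targets)",
         call. = FALSE)
  }
  binary_targets <- tibble::as_tibble(binary_targets)
  if (!setequal(binary_targets$var, binary_vars(schema))) {
    stop("binary_targets must cover exactly the binary schema variables",
         call. = FALSE)
  }
  props <- c(binary_targets$p_positive, binary_targets$p_negative)
  if (any(props <= 0 | props >= 1)) {
    stop("binary target proportions must lie in (0, 1)", call. = FALSE)
  }
  if (abs(sum(ses_props) - 1) > 1e-8 || any(ses_props <= 0)) {
    stop("ses_props must be positive and sum to 1", call. = FALSE)
  }
  structure(list(
    n_positive = as.integer(n_positive), n_negative = as.integer(n_negative),
    schema = schema,
    precision_positive = as.matrix(precision_positive),
    precision_negative = as.matrix(precision_negative),
    mean_shift = mean_shift, binary_targets = binary_targets,
    var_scale = tibble::as_tibble(var_scale), ses_props = ses_props,
    seed = as.integer(seed)
  ), class = "stratnet_design")
}

#' The default simulation design
#'
#' Emulates the study conditions the package targets: 78 + 131
#' participants, distinct planted sparse conditional-dependence
#' structures per stratum (hubs on self-directedness and
#' self-transcendence; 60 and 68 planted edges), stratum-specific mean
#' shifts on impulsivity, emotion dysregulation, distress, harm
#' avoidance (up) and self-directedness (down), and binary margins such
#' as a 48.7% vs 27.5% female proportion.
#'
#' @param seed Default seed carried by the design.
#' @return A `stratnet_design`.
#' @export
default_design <- function(seed = 1L) simulation_design(seed = seed)

#' A null simulation design
#'
#' Identity precision matrices, no mean shifts, identical binary margins
#' in the two strata: every variable is independent of every other and
#' the strata share one distribution. Used for calibration checks (the
#' `p < alpha` edge rule should retain a fraction `alpha` of edges; raw
#' group tests should reject at their nominal rate).
#'
#' @inheritParams default_design
#' @param n_positive,n_negative Stratum sizes.
#' @return A `stratnet_design`.
#' @export
null_design <- function(n_positive = 78L, n_negative = 131L, seed = 1L) {
  schema <- default_schema()
  simulation_design(
    n_positive = n_positive, n_negative = n_negative,
    precision_positive = diag(17), precision_negative = diag(17),
    mean_shift = stats::setNames(rep(0, 17), schema$name),
    binary_targets = tibble::tribble(
      ~var,            ~p_positive, ~p_negative,
      "Sex.Male",      0.65,        0.65,
      "Marit.NotMarr", 0.75,        0.75,
      "MentalDis",     0.30,        0.30,
      "Suicidal",      0.20,        0.20
    ),
    seed = seed
  )
}

# 2^31-safe substream seed derivation.
sub_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647)
}

# Draw one stratum as a tibble of schema variables (no stratum column).
generate_stratum <- function(design, stratum = c("positive", "negative"),
                             n = NULL, seed = NULL) {
  stratum <- match.arg(stratum)
  schema <- design$schema
  n <- n %||% if (stratum == "positive") design$n_positive else design$n_negative
  seed <- seed %||% sub_seed(design$seed, if (stratum == "positive") 1 else 2)
  P <- if (stratum == "positive") design$precision_positive else design$precision_negative
  Sigma <- stats::cov2cor(solve(P))
  shift <- if (stratum == "positive") design$mean_shift else design$mean_shift * 0

  Z <- withr::with_seed(seed,
    MASS::mvrnorm(n, mu = rep(0, nrow(schema)), Sigma = Sigma))
  Z <- matrix(Z, nrow = n, dimnames = list(NULL, schema$name))
  Z <- sweep(Z, 2, shift, "+")

  out <- tibble::as_tibble(Z)
  for (bv in binary_vars(schema)) {
    target <- design$binary_targets[design$binary_targets$var == bv, ]
    pr <- if (stratum == "positive") target$p_positive else target$p_negative
    # latent mean is `shift[bv]` (0 by design); cut so P(Z > c) = pr
    cut <- shift[[bv]] + stats::qnorm(1 - pr)
    out[[bv]] <- as.integer(Z[, bv] > cut)
  }
  if ("SES" %in% schema$name && "SES" %in% continuous_vars(schema)) {
    breaks <- c(-Inf, stats::qnorm(cumsum(design$ses_props)[-length(design$ses_props)]),
                Inf)
    out$SES <- as.numeric(cut(Z[, "SES"], breaks = breaks, labels = FALSE))
  }
  for (r in seq_len(nrow(design$var_scale))) {
    v <- design$var_scale$var[r]
    if (v %in% names(out) && !v %in% binary_vars(schema) && v != "SES") {
      out[[v]] <- design$var_scale$mean[r] + design$var_scale$sd[r] * out[[v]]
    }
  }
  out[schema$name]
}

#' Generate a synthetic cohort
#'
#' Draws both strata from the design (positive stratum first) and
#' returns a validated cohort table. Identical seeds give identical
#' tables; the two strata use independent substreams derived from the
#' single seed.
#'
#' @param design A `stratnet_design`.
#' @param seed Integer seed; defaults to the seed stored in the design.
#' @param stratum_column Name for the stratification column.
#' @return A `stratnet_cohort`.
#' @export
generate_cohort <- function(design, seed = design$seed, stratum_column = "FA") {
  pos <- generate_stratum(design, "positive", seed = sub_seed(seed, 1))
  neg <- generate_stratum(design, "negative", seed = sub_seed(seed, 2))
  pos[[stratum_column]] <- 1
  neg[[stratum_column]] <- 0
  as_cohort(dplyr::bind_rows(pos, neg), schema = design$schema,
            stratum_column = stratum_column)
}

#' Edge-recovery experiment for the estimate-then-threshold pipeline
#'
#' For each sample size, repeatedly draws the requested stratum from the
#' design, estimates its partial-correlation network with the `p < alpha`
#' rule, and compares the retained edge set with the planted support of
#' the design's precision matrix. Reports the mean sensitivity (planted
#' nonzero edges retained), the false-retention rate (planted zero edges
#' retained), the same restricted to strong planted edges
#' (`|r| >= 0.3`), the maximum absolute estimation error on strong
#' edges, and Monte-Carlo standard errors.
#'
#' @param design A `stratnet_design`.
#' @param n_grid Vector of per-stratum sample sizes (each must exceed
#'   19: with 15 controls, smaller samples leave no degrees of freedom).
#' @param replicates Number of Monte-Carlo replicates per sample size.
#' @param alpha Edge retention threshold.
#' @param stratum Which stratum's planted structure to probe.
#' @param seed Integer seed.
#' @return A tibble with one row per sample size.
#' @export
recovery_experiment <- function(design, n_grid, replicates = 20L,
                                alpha = 0.25,
                                stratum = c("positive", "negative"),
                                seed = 1L) {
  stratum <- match.arg(stratum)
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  if (any(n_grid <= 19)) {
    stop("sample sizes must exceed 19 (df = n - 17 must be positive and usable)",
         call. = FALSE)
  }
  P <- if (stratum == "positive") design$precision_positive else design$precision_negative
  truth <- planted_pcorr(P)
  ut <- upper.tri(truth)
  nonzero <- truth != 0 & ut
  zero <- truth == 0 & ut
  strong <- abs(truth) >= 0.3 & ut

  purrr::map_dfr(n_grid, function(n) {
    sens <- fr <- sens_strong <- err_strong <- numeric(replicates)
    for (r in seq_len(replicates)) {
      dat <- generate_stratum(design, stratum, n = n,
                              seed = sub_seed(seed, 1000 * n + r))
      pc <- partial_correlations(dat)
      keep <- pc$p < alpha
      sens[r] <- if (any(nonzero)) mean(keep[nonzero]) else NA_real_
      fr[r] <- if (any(zero)) mean(keep[zero]) else NA_real_
      sens_strong[r] <- if (any(strong)) mean(keep[strong]) else NA_real_
      err_strong[r] <- if (any(strong)) max(abs(pc$r[strong] - truth[strong])) else NA_real_
    }
    tibble::tibble(
      n = n,
      sensitivity = mean(sens),
      se_sensitivity = stats::sd(sens) / sqrt(replicates),
      false_retention = mean(fr),
      se_false_retention = stats::sd(fr) / sqrt(replicates),
      sensitivity_strong = mean(sens_strong),
      max_abs_error_strong = mean(err_strong)
    )
  })
}

#' @export
print.stratnet_design <- function(x, ...) {
  cat("<stratnet simulation design> n = ", x$n_positive, " + ", x$n_negative,
      "; planted edges: ",
      sum(x$precision_positive[upper.tri(x$precision_positive)] != 0), " (positive) / ",
      sum(x$precision_negative[upper.tri(x$precision_negative)] != 0), " (negative)\n",
      sep = "")
  invisible(x)
}
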