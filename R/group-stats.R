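#' Pearson chi-square test with Cramer's V
#'
#' Uncorrected (no Yates continuity correction) Pearson chi-square on an
#' r x c contingency table, with `V = sqrt(chi2 / (N * (min(r, c) - 1)))`.
#' The effect-size convention (V above 0.20 read as at least
#' mild-to-moderate) presumes the uncorrected statistic.
#'
#' @param tab An r x c matrix of non-negative counts (at least 2 x 2).
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `cramers_v`,
#'   `effect_label`.
#' @export
chi_square_test <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("counts must be non-negative", call. = FALSE)
  if (nrow(tab) < 2 || ncol(tab) < 2) stop("table must be at least 2 x 2", call. = FALSE)
  if (sum(tab) == 0) stop("table total must be positive", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero row/column margin: expected counts undefined", call. = FALSE)
  }
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  v <- sqrt(unname(res$statistic) / (sum(tab) * (min(dim(tab)) - 1)))
  tibble::tibble(
    statistic = unname(res$statistic),
    df = unname(res$parameter),
    p_value = unname(res$p.value),
    cramers_v = v,
    effect_label = effect_label_v(v)
  )
}

#' Pooled-variance t-test with Cohen's d
#'
#' Two-sided Student (equal-variance) t-test; `d` is the mean difference
#' divided by the pooled standard deviation, so the test statistic and
#' the effect size share one variance estimate.
#'
#' @param group_a,group_b Numeric vectors, each with at least two values.
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `cohens_d`,
#'   `effect_label`.
#' @export
cohens_t_test <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  na <- length(group_a); nb <- length(group_b)
  sp2 <- ((na - 1) * stats::var(group_a) + (nb - 1) * stats::var(group_b)) /
    (na + nb - 2)
  if (sp2 == 0) stop("zero pooled variance", call. = FALSE)
  res <- stats::t.test(group_a, group_b, var.equal = TRUE)
  d <- (mean(group_a) - mean(group_b)) / sqrt(sp2)
  tibble::tibble(
    statistic = unname(res$statistic),
    df = unname(res$parameter),
    p_value = unname(res$p.value),
    cohens_d = d,
    effect_label = effect_label_d(d)
  )
}

effect_label_v <- function(v) {
  dplyr::case_when(v > 0.35 ~ "moderate-large",
                   v > 0.20 ~ "mild-moderate",
                   TRUE ~ "below")
}

effect_label_d <- function(d) {
  dplyr::case_when(abs(d) > 0.80 ~ "moderate-large",
                   abs(d) > 0.50 ~ "mild-moderate",
                   TRUE ~ "below")
}

#' Finner step-down p-value adjustment
#'
#' Orders the p-values ascending and sets
#' `p~_(i) = max_{j <= i} (1 - (1 - p_(j))^(m/j))`, mapped back to the
#' input order and clipped to `[0, 1]`. Uniformly less conservative than
#' Bonferroni while still controlling the family-wise error rate.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param m Family size; defaults to `length(p_values)` and must be at
#'   least that.
#' @return Adjusted p-values in the input order.
#' @export
finner_adjust <- function(p_values, m = length(p_values)) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(p_values < 0 | p_values > 1 | is.na(p_values))) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  if (m < length(p_values)) stop("m must be >= length(p_values)", call. = FALSE)
  ord <- order(p_values)
  p_sorted <- p_values[ord]
  i <- seq_along(p_sorted)
  adj <- cummax(1 - (1 - p_sorted)^(m / i))
  adj <- pmin(pmax(adj, 0), 1)
  out <- numeric(length(p_values))
  out[ord] <- adj
  out
}

# Round half up to `digits` decimals (printed-percentage convention,
# where e.g. 48.65 -> 48.7 regardless of binary representation).
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Descriptive group-comparison battery
#'
#' Builds the descriptive table comparing the two strata: for binary
#' variables, counts and within-column percentages (rounded half-up to
#' one decimal) with a 2 x 2 chi-square and Cramer's V; for continuous
#' variables, mean (SD) per column with a pooled t-test and Cohen's d.
#' Finner's step-down correction is applied across the whole family of
#' tests run in this invocation.
#'
#' @param cohort A `stratnet_cohort` with both strata non-empty.
#' @return A list with two tibbles: `comparisons` (one row per variable:
#'   test, statistic, df, raw and Finner-adjusted p-values, effect size
#'   and label) and `descriptives` (counts/percentages or mean/SD for
#'   total, negative and positive stratum columns).
#' @export
table_one <- function(cohort) {
  schema <- cohort_schema(cohort)
  stratum_column <- cohort_stratum_column(cohort)
  flag <- cohort[[stratum_column]]
  if (!any(flag == 1) || !any(flag == 0)) {
    stop("both strata must be non-empty", call. = FALSE)
  }
  data <- tibble::as_tibble(cohort)
  pos <- data[flag == 1, ]
  neg <- data[flag == 0, ]

  comp_rows <- list()
  desc_rows <- list()
  for (v in schema$name) {
    def <- schema[schema$name == v, ]
    if (def$mtype == "binary") {
      tab <- rbind(neg_counts = c(sum(neg[[v]] == 1), sum(neg[[v]] == 0)),
                   pos_counts = c(sum(pos[[v]] == 1), sum(pos[[v]] == 0)))
      ct <- chi_square_test(tab)
      comp_rows[[v]] <- tibble::tibble(
        variable = v, test = "chi_square",
        statistic = ct$statistic, df = ct$df, p_raw = ct$p_value,
        effect_size = ct$cramers_v, effect_label = ct$effect_label
      )
      lv <- c(def$positive_level, paste0("not ", def$positive_level))
      for (side in 1:2) {
        val <- if (side == 1) 1 else 0
        desc_rows[[paste(v, side)]] <- tibble::tibble(
          variable = v, level = lv[side], type = "count_pct",
          total_n = sum(data[[v]] == val),
          total_pct = round_half_up(100 * sum(data[[v]] == val) / nrow(data)),
          negative_n = sum(neg[[v]] == val),
          negative_pct = round_half_up(100 * sum(neg[[v]] == val) / nrow(neg)),
          positive_n = sum(pos[[v]] == val),
          positive_pct = round_half_up(100 * sum(pos[[v]] == val) / nrow(pos)),
          total_mean = NA_real_, total_sd = NA_real_,
          negative_mean = NA_real_, negative_sd = NA_real_,
          positive_mean = NA_real_, positive_sd = NA_real_
        )
      }
    } else {
      tt <- cohens_t_test(pos[[v]], neg[[v]])
      comp_rows[[v]] <- tibble::tibble(
        variable = v, test = "t_test",
        statistic = tt$statistic, df = tt$df, p_raw = tt$p_value,
        effect_size = tt$cohens_d, effect_label = tt$effect_label
      )
      desc_rows[[v]] <- tibble::tibble(
        variable = v, level = NA_character_, type = "mean_sd",
        total_n = NA_integer_, total_pct = NA_real_,
        negative_n = NA_integer_, negative_pct = NA_real_,
        positive_n = NA_integer_, positive_pct = NA_real_,
        total_mean = mean(data[[v]]), total_sd = stats::sd(data[[v]]),
        negative_mean = mean(neg[[v]]), negative_sd = stats::sd(neg[[v]]),
        positive_mean = mean(pos[[v]]), positive_sd = stats::sd(pos[[v]])
      )
    }
  }
  comparisons <- dplyr::bind_rows(comp_rows)
  comparisons$p_adjusted <- finner_adjust(comparisons$p_raw)
  comparisons <- comparisons[, c("variable", "test", "statistic", "df",
                                 "p_raw", "p_adjusted", "effect_size",
                                 "effect_label")]
  list(comparisons = comparisons, descriptives = dplyr::bind_rows(desc_rows))
}
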