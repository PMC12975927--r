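#' Build a validated cohort table
#'
#' A cohort table is a tibble with one row per participant, the schema
#' variables as numeric columns (in schema order) and a binary
#' stratification column (1 = stratum of interest, e.g. FA+; 0 = the
#' complement). All validation of the loader applies: no missing cells
#' (unless `listwise_deletion = TRUE`, which drops incomplete rows),
#' binary columns restricted to \{0, 1\}, continuous columns finite.
#'
#' @param data A data frame containing every schema variable plus the
#'   stratum column.
#' @param schema Variable schema, as produced by [default_schema()].
#' @param stratum_column Name of the binary stratification column.
#' @param listwise_deletion Drop rows with missing values instead of
#'   raising an error. Default `FALSE`: missing data are a hard error.
#' @return A tibble of class `stratnet_cohort` with columns in schema
#'   order followed by the stratum column; the schema and stratum-column
#'   name are carried as attributes.
#' @export
as_cohort <- function(data, schema = default_schema(),
                      stratum_column = "FA", listwise_deletion = FALSE) {
  schema <- variable_schema(schema)
  data <- tibble::as_tibble(data)

  needed <- c(schema$name, stratum_column)
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    stop("input table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  data <- data[needed]

  not_num <- names(data)[!vapply(data, is.numeric, logical(1))]
  for (col in not_num) {
    raw <- data[[col]]
    conv <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(conv) & !is.na(raw) & trimws(as.character(raw)) != "")
    if (length(bad) > 0) {
      stop("non-numeric value in column '", col, "' at row ", bad[1],
           call. = FALSE)
    }
    data[[col]] <- conv
  }

  incomplete <- !stats::complete.cases(data)
  if (any(incomplete)) {
    if (listwise_deletion) {
      data <- data[!incomplete, ]
    } else {
      stop("missing value(s) in row(s) ",
           paste(utils::head(which(incomplete), 5), collapse = ", "),
           "; set listwise_deletion = TRUE to drop incomplete rows",
           call. = FALSE)
    }
  }
  if (nrow(data) == 0) stop("cohort has no complete rows", call. = FALSE)

  for (col in c(binary_vars(schema), stratum_column)) {
    vals <- data[[col]]
    if (!all(vals %in% c(0, 1))) {
      stop("binary column '", col, "' contains value(s) outside {0, 1}",
           call. = FALSE)
    }
  }
  for (col in continuous_vars(schema)) {
    if (!all(is.finite(data[[col]]))) {
      stop("non-finite value in continuous column '", col, "'",
           call. = FALSE)
    }
  }

  structure(data,
            schema = schema,
            stratum_column = stratum_column,
            class = c("stratnet_cohort", class(tibble::tibble())))
}

#' Load a participant-level CSV into a cohort table
#'
#' Reads a comma-separated UTF-8 file with a mandatory header row and `.`
#' as decimal separator, validates it against the schema and returns a
#' cohort table. Column order in the result follows the schema, not the
#' file.
#'
#' @param path Path to the CSV file.
#' @inheritParams as_cohort
#' @return A `stratnet_cohort` tibble; see [as_cohort()].
#' @export
load_cohort <- function(path, schema = default_schema(),
                        stratum_column = "FA", listwise_deletion = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  as_cohort(raw, schema = schema, stratum_column = stratum_column,
            listwise_deletion = listwise_deletion)
}

#' Write a cohort table to CSV
#'
#' @param cohort A `stratnet_cohort` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(tibble::as_tibble(cohort), path)
  invisible(path)
}

cohort_schema <- function(cohort) attr(cohort, "schema", exact = TRUE)
cohort_stratum_column <- function(cohort) attr(cohort, "stratum_column", exact = TRUE)

#' Split a cohort by its stratification flag
#'
#' Partitions the cohort into the positive stratum (flag 1, e.g. FA+) and
#' the negative stratum (flag 0, e.g. FA-). An empty stratum is an error;
#' a stratum with fewer than 20 participants triggers a warning because
#' partial-correlation network estimation with 15 controls is unstable at
#' such sizes.
#'
#' @param cohort A `stratnet_cohort` tibble.
#' @return A named list with elements `positive` and `negative`, each a
#'   `stratnet_cohort` restricted to one stratum.
#' @export
split_by_stratum <- function(cohort) {
  stratum_column <- cohort_stratum_column(cohort)
  schema <- cohort_schema(cohort)
  flag <- cohort[[stratum_column]]
  parts <- list(positive = tibble::as_tibble(cohort)[flag == 1, ],
                negative = tibble::as_tibble(cohort)[flag == 0, ])
  for (nm in names(parts)) {
    if (nrow(parts[[nm]]) == 0) {
      stop("stratum '", nm, "' is empty", call. = FALSE)
    }
    if (nrow(parts[[nm]]) < 20) {
      warning("stratum '", nm, "' has fewer than 20 rows; ",
              "network estimation will be unstable", call. = FALSE)
    }
  }
  lapply(parts, as_cohort, schema = schema, stratum_column = stratum_column)
}

#' @export
print.stratnet_cohort <- function(x, ...) {
  stratum_column <- cohort_stratum_column(x)
  n_pos <- sum(x[[stratum_column]] == 1)
  cat("<stratnet cohort> ", nrow(x), " participants (",
      n_pos, " ", stratum_column, "+ / ", nrow(x) - n_pos, " ",
      stratum_column, "-), ",
      nrow(cohort_schema(x)), " analysis variables\n", sep = "")
  NextMethod()
}
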