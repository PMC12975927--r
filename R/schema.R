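#' The default 17-node clinical variable schema
#'
#' Catalog of the variables entering the network: four sociodemographic
#' nodes, six psychopathology nodes and the seven temperament/character
#' dimensions of the TCI-R. Binary nodes record which level is coded 1
#' (`positive_level`); the node label names that level (e.g. `Sex. Male`
#' means male = 1, so a positive edge sign refers to being male).
#'
#' Coding conventions for the default schema:
#' * sex is coded male = 1;
#' * marital status is binarized: married/couple = 0 vs single or
#'   divorced/separated = 1 (`Marit. NotMarr`);
#' * the social position index enters as a single ordinal-as-continuous
#'   score 1--5 (1 = high ... 5 = low);
#' * duration of the behavioral-addiction problem is continuous, in years.
#'
#' @return A tibble with one row per variable and columns `name`, `label`,
#'   `dimension` (`sociodemographic`, `psychopathology` or `personality`),
#'   `mtype` (`binary` or `continuous`) and `positive_level` (`NA` for
#'   continuous variables).
#' @export
#' @examples
#' default_schema()
default_schema <- function() {
  variable_schema(tibble::tribble(
    ~name,           ~label,            ~dimension,         ~mtype,       ~positive_level,
    "Sex.Male",      "Sex. Male",       "sociodemographic", "binary",     "male",
    "Age",           "Age",             "sociodemographic", "continuous", NA,
    "Marit.NotMarr", "Marit. NotMarr",  "sociodemographic", "binary",     "not married",
    "SES",           "SES",             "sociodemographic", "continuous", NA,
    "Impulsivity",   "Impulsivity",     "psychopathology",  "continuous", NA,
    "Emotion",       "Emotion",         "psychopathology",  "continuous", NA,
    "Psy.Distress",  "Psy. Distress",   "psychopathology",  "continuous", NA,
    "MentalDis",     "MentalDis",       "psychopathology",  "binary",     "present",
    "Suicidal",      "Suicidal",        "psychopathology",  "binary",     "present",
    "DurationBA",    "DurationBA",      "psychopathology",  "continuous", NA,
    "TCI.novelty",   "TCI.novelty",     "personality",      "continuous", NA,
    "TCI.harm",      "TCI.harm",        "personality",      "continuous", NA,
    "TCI.reward",    "TCI.reward",      "personality",      "continuous", NA,
    "TCI.persis",    "TCI.persis",      "personality",      "continuous", NA,
    "TCI.directed",  "TCI.directed",    "personality",      "continuous", NA,
    "TCI.coopera",   "TCI.coopera",     "personality",      "continuous", NA,
    "TCI.transcen",  "TCI.transcen",    "personality",      "continuous", NA
  ))
}

#' Validate a variable schema
#'
#' @param entries A data frame with columns `name`, `label`, `dimension`,
#'   `mtype` and `positive_level`.
#' @return The validated schema as a tibble.
#' @export
variable_schema <- function(entries) {
  entries <- tibble::as_tibble(entries)
  required <- c("name", "label", "dimension", "mtype", "positive_level")
  missing <- setdiff(required, names(entries))
  if (length(missing) > 0) {
    stop("schema is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(entries$name)) {
    stop("schema variable names must be unique", call. = FALSE)
  }
  bad_dim <- setdiff(entries$dimension,
                     c("sociodemographic", "psychopathology", "personality"))
  if (length(bad_dim) > 0) {
    stop("unknown dimension(s): ", paste(bad_dim, collapse = ", "),
         call. = FALSE)
  }
  bad_type <- setdiff(entries$mtype, c("binary", "continuous"))
  if (length(bad_type) > 0) {
    stop("unknown mtype(s): ", paste(bad_type, collapse = ", "),
         call. = FALSE)
  }
  no_level <- entries$mtype == "binary" & is.na(entries$positive_level)
  if (any(no_level)) {
    stop("binary variable(s) without a declared positive_level: ",
         paste(entries$name[no_level], collapse = ", "), call. = FALSE)
  }
  entries[required]
}

binary_vars <- function(schema) schema$name[schema$mtype == "binary"]
continuous_vars <- function(schema) schema$name[schema$mtype == "continuous"]
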