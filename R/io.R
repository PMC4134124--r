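#' Read and write the pipeline's CSV interchange formats
#'
#' Plain-CSV schemas shared by all stages:
#' * `registry.csv`: `person_id, sex, birth_date, cover_start, cover_end`
#'   (dates ISO-8601).
#' * `encounters.csv`: `person_id, date, source, icd_version, code` with
#'   `source` in `claim`/`discharge` and `icd_version` 9 or 10. Hospital
#'   abstracts carrying several diagnosis codes must be exploded into one row
#'   per code upstream; each row carries exactly one code.
#' * `population.csv`: `year, age_group, sex, count`.
#' * `cases.csv`: the output of [ascertain_cases()].
#'
#' @param path file path.
#' @return a tibble with typed columns.
#' @name claims_io
NULL

read_csv_checked <- function(path, cols, what) {
  if (!file.exists(path)) {
    stop(sprintf("configuration error: %s file not found: %s", what, path),
         call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  check_columns(df, cols, what)
  as_tibble(df)
}

#' @rdname claims_io
#' @export
read_registry_csv <- function(path) {
  df <- read_csv_checked(path, c("person_id", "sex", "birth_date",
                                 "cover_start", "cover_end"), "registry")
  df$birth_date <- as.Date(df$birth_date)
  df$cover_start <- as.Date(df$cover_start)
  df$cover_end <- as.Date(df$cover_end)
  df
}

#' @rdname claims_io
#' @export
read_encounters_csv <- function(path) {
  df <- read_csv_checked(path, c("person_id", "date", "source", "icd_version",
                                 "code"), "encounters")
  df$date <- as.Date(df$date)
  df$icd_version <- as.integer(df$icd_version)
  bad <- setdiff(unique(df$source), c("claim", "discharge"))
  if (length(bad) > 0) {
    stop("encounters `source` must be 'claim' or 'discharge'; found: ",
         paste(bad, collapse = ", "))
  }
  df
}

#' @rdname claims_io
#' @export
read_population_csv <- function(path) {
  read_csv_checked(path, c("year", "age_group", "sex", "count"), "population")
}

#' @rdname claims_io
#' @export
read_cases_csv <- function(path) {
  df <- read_csv_checked(path, c("person_id", "diagnosis_date",
                                 "diagnosis_year", "score", "category",
                                 "n_claims", "n_discharges"), "cases")
  df$diagnosis_date <- as.Date(df$diagnosis_date)
  df
}

#' Read a standard population for direct standardization
#'
#' Accepts either a `weight` column (non-negative, summing to 1) or a raw
#' `population` count column which is normalized to weights. Lines starting
#' with `#` are comments (used for provenance notes in the bundled fixture).
#'
#' @param path CSV with `age_group` and `weight` or `population`.
#' @return tibble `age_group`, `weight`.
#' @export
read_standard_population <- function(path) {
  df <- read_csv_checked(path, "age_group", "standard population")
  if ("weight" %in% names(df)) {
    out <- tibble(age_group = df$age_group, weight = as.numeric(df$weight))
  } else if ("population" %in% names(df)) {
    p <- as.numeric(df$population)
    out <- tibble(age_group = df$age_group, weight = p / sum(p))
  } else {
    stop("standard population needs a `weight` or `population` column")
  }
  if (any(out$weight < 0) || abs(sum(out$weight) - 1) > 1e-9) {
    stop("standard population weights must be non-negative and sum to 1")
  }
  out
}

#' @rdname claims_io
#' @param x tibble to write.
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a simulated cohort to a directory of CSV files
#'
#' Emits `registry.csv`, `encounters.csv`, `population.csv` and `truth.csv`
#' in the interchange schemas above.
#'
#' @param cohort list from [simulate_cohort()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_table_csv(cohort$registry, file.path(dir, "registry.csv"))
  write_table_csv(cohort$encounters, file.path(dir, "encounters.csv"))
  write_table_csv(cohort$population, file.path(dir, "population.csv"))
  write_table_csv(cohort$truths, file.path(dir, "truth.csv"))
  invisible(dir)
}
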