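#' Summarise incident cases by category and sex
#'
#' Totals and shares of ascertained cases: per-disease counts with their
#' percentage of the IBD total, and within each disease the split between
#' women and men. Percentages are rounded half-up to one decimal, matching
#' report conventions.
#'
#' @param cases case records.
#' @param registry person table supplying `sex`.
#' @return tibble `disease` (CD/UC/IBDU/IBD), `n`, `pct_of_ibd`, `n_women`,
#'   `pct_women`, `n_men`, `pct_men`.
#' @export
summarise_categories <- function(cases, registry) {
  joined <- dplyr::inner_join(
    cases, dplyr::select(registry, "person_id", "sex"), by = "person_id"
  )
  per <- lapply(c("CD", "UC", "IBDU", "IBD"), function(d) {
    sub <- if (d == "IBD") joined else joined[joined$category == d, ]
    n <- nrow(sub)
    nw <- sum(sub$sex == "female")
    tibble(disease = d, n = n,
           pct_of_ibd = round_half_up(100 * n / max(1, nrow(joined)), 1),
           n_women = nw,
           pct_women = if (n > 0) round_half_up(100 * nw / n, 1) else NA_real_,
           n_men = n - nw,
           pct_men = if (n > 0) round_half_up(100 * (n - nw) / n, 1) else NA_real_)
  })
  dplyr::bind_rows(per)
}

#' Incident-case counts and column percentages by sex and age group
#'
#' The classic case-mix table: for each sex and disease, counts per 10-year
#' age bin with the percentage of that sex-disease column, plus an `all` row.
#' Column percentages sum to 100 up to rounding (half-up, one decimal).
#'
#' @param cases case records.
#' @param registry person table.
#' @param grouping an [age_grouping()].
#' @return long tibble `sex`, `age_group` (bin label or `"all"`), `disease`,
#'   `n`, `pct`.
#' @export
build_table2 <- function(cases, registry, grouping = default_age_grouping()) {
  cube <- tabulate_cases(cases, registry, grouping, add_ibd = FALSE)
  cells <- cube |>
    dplyr::group_by(.data$sex, .data$age_group, .data$disease) |>
    dplyr::summarise(n = sum(.data$n), .groups = "drop") |>
    dplyr::group_by(.data$sex, .data$disease) |>
    dplyr::mutate(total = sum(.data$n),
                  pct = ifelse(.data$total > 0,
                               round_half_up(100 * .data$n / .data$total, 1),
                               NA_real_)) |>
    dplyr::ungroup() |>
    dplyr::mutate(age_group = as.character(.data$age_group)) |>
    dplyr::select("sex", "age_group", "disease", "n", "pct")
  totals <- cells |>
    dplyr::group_by(.data$sex, .data$disease) |>
    dplyr::summarise(age_group = "all", n = sum(.data$n),
                     pct = ifelse(sum(.data$n) > 0, 100, NA_real_),
                     .groups = "drop")
  dplyr::bind_rows(cells, totals) |>
    dplyr::arrange(.data$sex, .data$disease)
}

#' Annual age-standardized rate table by sex and disease
#'
#' Reshapes the standardized rows of a rate table into the publication shape:
#' one row per study year, columns `<sex>_<disease>` (women, men, sexes
#' combined x CD, UC, IBDU), values rounded half-up to one decimal. Years are
#' strictly ascending; a missing year cell is a coverage error.
#'
#' @param rate_table output of [build_rate_tables()].
#' @param diseases diseases to include as columns.
#' @return wide tibble with a `year` column.
#' @export
build_table3 <- function(rate_table, diseases = c("CD", "UC", "IBDU")) {
  asr <- rate_table |>
    dplyr::filter(.data$rate_type == "asr", .data$disease %in% diseases) |>
    dplyr::mutate(
      sex = c(female = "women", male = "men", both = "combined")[.data$sex]
    )
  years <- seq(min(rate_table$year), max(rate_table$year))
  expected <- length(years) * length(diseases) * 3
  if (nrow(asr) != expected) {
    stop("coverage error: missing year cells in the standardized rate table")
  }
  asr |>
    dplyr::mutate(rate = round_half_up(.data$rate, 1),
                  col = paste(.data$sex, .data$disease, sep = "_"),
                  sex = factor(.data$sex, levels = c("women", "men", "combined"))) |>
    dplyr::arrange(.data$sex, match(.data$disease, diseases)) |>
    dplyr::select("year", "col", "rate") |>
    tidyr::pivot_wider(names_from = "col", values_from = "rate") |>
    dplyr::arrange(.data$year)
}

#' Data series behind the standard figures
#'
#' Tidy long-format series ready for plotting: annual age-standardized rates
#' by disease including the IBD union (sexes combined); crude age-specific
#' annual rates by disease; and the CD:UC incident-count ratio by age group
#' and sex. With shared standard weights the IBD series equals the sum of the
#' CD, UC and IBDU series (linearity of the weighted sum) — asserted in the
#' test suite.
#'
#' @param rate_table output of [build_rate_tables()].
#' @param cases,registry inputs for the ratio series.
#' @param grouping an [age_grouping()] for the ratio series.
#' @return list of tibbles `asr_by_year`, `age_specific`, `cd_uc_ratio`.
#' @export
build_figure_series <- function(rate_table, cases, registry,
                                grouping = default_age_grouping()) {
  asr_by_year <- rate_table |>
    dplyr::filter(.data$rate_type == "asr", .data$sex == "both") |>
    dplyr::select("year", "disease", "rate")
  age_specific <- rate_table |>
    dplyr::filter(.data$rate_type == "crude", .data$sex == "both") |>
    dplyr::select("year", "age_group", "disease", "rate")
  list(asr_by_year = asr_by_year, age_specific = age_specific,
       cd_uc_ratio = cd_uc_ratio_by_age(cases, registry, grouping))
}
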