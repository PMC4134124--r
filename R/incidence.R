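ALL_DISEASES <- c("CD", "UC", "IBDU", "IBD")

#' Tabulate incident cases by year, age group, sex and disease
#'
#' Builds the complete, zero-filled contingency cube of case counts. Age at
#' diagnosis is the calendar-year age, `diagnosis_year - birth_year`,
#' consistent with annual denominators.
#'
#' @param cases case records from [ascertain_cases()].
#' @param registry person table supplying `sex` and `birth_date`.
#' @param grouping an [age_grouping()].
#' @param years calendar years the cube must cover (defaults to the span of
#'   the observed diagnosis years).
#' @param add_ibd if `TRUE`, append `IBD` rows equal to the CD + UC + IBDU
#'   sum per cell.
#' @return tibble `year`, `age_group`, `sex`, `disease`, `n`, complete over
#'   the cross of its margins.
#' @export
tabulate_cases <- function(cases, registry, grouping = default_age_grouping(),
                           years = NULL, add_ibd = TRUE) {
  check_columns(cases, c("person_id", "diagnosis_year", "category"), "cases")
  if (!all(cases$person_id %in% registry$person_id)) {
    stop("data error: case person missing from registry")
  }
  if (is.null(years)) {
    years <- if (nrow(cases) == 0) integer(0) else
      seq(min(cases$diagnosis_year), max(cases$diagnosis_year))
  }
  diseases <- c("CD", "UC", "IBDU")
  joined <- cases |>
    dplyr::inner_join(dplyr::select(registry, "person_id", "sex", "birth_date"),
                      by = "person_id") |>
    dplyr::mutate(
      age = .data$diagnosis_year - year_of(.data$birth_date),
      age_group = assign_age_group(.data$age, grouping)
    )
  cube <- joined |>
    dplyr::count(year = .data$diagnosis_year, .data$age_group, .data$sex,
                 disease = .data$category) |>
    tidyr::complete(year = years,
                    age_group = factor(grouping$labels,
                                       levels = grouping$labels),
                    sex = c("female", "male"), disease = diseases,
                    fill = list(n = 0L)) |>
    dplyr::filter(.data$year %in% years)
  if (add_ibd) {
    ibd <- cube |>
      dplyr::group_by(.data$year, .data$age_group, .data$sex) |>
      dplyr::summarise(disease = "IBD", n = sum(.data$n), .groups = "drop")
    cube <- dplyr::bind_rows(cube, ibd)
  }
  dplyr::arrange(cube, .data$year, .data$age_group, .data$sex, .data$disease)
}

#' Crude incidence rate per 100,000
#'
#' `100000 * cases / population`. A cell with zero population and zero cases
#' yields rate 0 and is flagged via the `"zero_denominator"` attribute; zero
#' population with positive cases is an error (the rate is undefined).
#'
#' @param cases,population non-negative numeric vectors (recycled as usual).
#' @return numeric rates per 100,000 with attribute `zero_denominator`.
#' @examples
#' crude_rate(23, 46000) # 50
#' @export
crude_rate <- function(cases, population) {
  if (any(population == 0 & cases > 0)) {
    stop("undefined rate: positive case count with zero population")
  }
  zero <- population == 0
  out <- ifelse(zero, 0, 1e5 * cases / population)
  attr(out, "zero_denominator") <- zero
  out
}

#' Direct age standardization
#'
#' Weighted average of age-specific rates using a fixed standard population's
#' age weights: `sum_a weight(a) * rate(a)`. Weights must be non-negative and
#' sum to 1; every age group with positive weight must have a (possibly
#' explicitly zero) rate.
#'
#' @param rates age-specific rates: a tibble with columns `age_group` and
#'   `rate`, or a named numeric vector.
#' @param std standard population: a tibble with columns `age_group` and
#'   `weight`, or a named numeric vector; see [canada_2006_standard()].
#' @return the directly standardized rate (same units as the input rates).
#' @export
age_standardize <- function(rates, std) {
  if (!is.data.frame(rates)) {
    rates <- tibble(age_group = names(rates), rate = as.numeric(rates))
  }
  if (!is.data.frame(std)) {
    std <- tibble(age_group = names(std), weight = as.numeric(std))
  }
  check_columns(rates, c("age_group", "rate"), "rates")
  check_columns(std, c("age_group", "weight"), "standard population")
  if (any(std$weight < 0) || abs(sum(std$weight) - 1) > 1e-9) {
    stop("standard weights must be non-negative and sum to 1")
  }
  j <- dplyr::left_join(std, dplyr::mutate(rates, age_group = as.character(.data$age_group)),
                        by = "age_group")
  bad <- j$weight > 0 & is.na(j$rate)
  if (any(bad)) {
    stop("coverage error: no rate for age group(s) with positive weight: ",
         paste(j$age_group[bad], collapse = ", "))
  }
  sum(j$weight * dplyr::coalesce(j$rate, 0))
}

#' Bundled standard population (2006 Canada, synthetic approximation)
#'
#' Age-group weights for direct standardization, shipped as
#' `canada_2006_synthetic_standard.csv`. The counts approximate the published
#' 2006 Canadian Census age distribution aggregated to 10-year bins; they are
#' a synthetic stand-in recorded for reproducibility, not an official
#' extract, and any standard can be substituted via
#' [read_standard_population()].
#'
#' @return tibble with `age_group` and `weight` (weights sum to 1).
#' @export
canada_2006_standard <- function() {
  path <- system.file("extdata", "canada_2006_synthetic_standard.csv",
                      package = "ibdclaims", mustWork = TRUE)
  read_standard_population(path)
}

#' Build crude and age-standardized rate tables
#'
#' For each study year, disease (CD, UC, IBDU and their union IBD) and sex
#' level (female, male, both), computes crude age-specific rates per 100,000
#' and the directly age-standardized rate (rows with `age_group == "all"`,
#' `rate_type == "asr"`). Cells with no population and no cases carry an
#' explicit zero rate (flagged `zero_denominator`).
#'
#' @param cases case records from [ascertain_cases()].
#' @param registry person table.
#' @param population denominator tibble (`year`, `age_group`, `sex`, `count`).
#' @param std standard population weights (see [age_standardize()]).
#' @param grouping an [age_grouping()] matching the population table and
#'   standard.
#' @param years study years; defaults to the years present in `population`.
#' @return long tibble: `year`, `age_group` (bin label or `"all"`), `sex`
#'   (`female`/`male`/`both`), `disease`, `cases`, `population`, `rate`,
#'   `rate_type` (`"crude"` or `"asr"`), `zero_denominator`.
#' @export
build_rate_tables <- function(cases, registry, population,
                              std = canada_2006_standard(),
                              grouping = default_age_grouping(),
                              years = NULL) {
  check_columns(population, c("year", "age_group", "sex", "count"),
                "population table")
  if (is.null(years)) years <- sort(unique(population$year))
  cube <- tabulate_cases(cases, registry, grouping, years = years)

  pop <- population |>
    dplyr::filter(.data$year %in% years) |>
    dplyr::mutate(age_group = as.character(.data$age_group)) |>
    tidyr::complete(year = years, age_group = grouping$labels,
                    sex = c("female", "male"), fill = list(count = 0))
  pop_both <- pop |>
    dplyr::group_by(.data$year, .data$age_group) |>
    dplyr::summarise(sex = "both", count = sum(.data$count), .groups = "drop")
  pop <- dplyr::bind_rows(pop, pop_both)

  cube_both <- cube |>
    dplyr::group_by(.data$year, .data$age_group, .data$disease) |>
    dplyr::summarise(sex = "both", n = sum(.data$n), .groups = "drop")
  cube <- dplyr::bind_rows(dplyr::mutate(cube, age_group = as.character(.data$age_group)),
                           dplyr::mutate(cube_both, age_group = as.character(.data$age_group)))

  spec_rates <- cube |>
    dplyr::inner_join(pop, by = c("year", "age_group", "sex")) |>
    dplyr::rename(cases = "n", population = "count")
  r <- crude_rate(spec_rates$cases, spec_rates$population)
  spec_rates$rate <- as.numeric(r)
  spec_rates$zero_denominator <- attr(r, "zero_denominator")
  spec_rates$rate_type <- "crude"

  if (!is.data.frame(std)) {
    std <- tibble(age_group = names(std), weight = as.numeric(std))
  }
  asr <- spec_rates |>
    dplyr::group_by(.data$year, .data$sex, .data$disease) |>
    dplyr::summarise(
      asr = age_standardize(dplyr::pick("age_group", "rate"), std),
      cases = sum(.data$cases),
      population = sum(.data$population),
      .groups = "drop"
    ) |>
    dplyr::mutate(age_group = "all", rate = .data$asr,
                  zero_denominator = FALSE, rate_type = "asr") |>
    dplyr::select(-"asr")
  dplyr::bind_rows(spec_rates, asr) |>
    dplyr::select("year", "age_group", "sex", "disease", "cases",
                  "population", "rate", "rate_type", "zero_denominator") |>
    dplyr::arrange(.data$year, .data$sex, .data$disease)
}

#' Ratio of CD to UC incident cases by age group
#'
#' Within an age/sex cell the population denominator cancels, so the
#' incidence ratio equals the ratio of incident counts. Cells with no UC
#' cases are flagged undefined (`NA` ratio), never an error.
#'
#' @param cases case records.
#' @param registry person table.
#' @param grouping an [age_grouping()].
#' @return tibble `age_group`, `sex` (including `"both"`), `cd`, `uc`,
#'   `ratio`, `undefined`.
#' @export
cd_uc_ratio_by_age <- function(cases, registry,
                               grouping = default_age_grouping()) {
  cube <- tabulate_cases(cases, registry, grouping, add_ibd = FALSE)
  by_cell <- cube |>
    dplyr::filter(.data$disease %in% c("CD", "UC")) |>
    dplyr::group_by(.data$age_group, .data$sex, .data$disease) |>
    dplyr::summarise(n = sum(.data$n), .groups = "drop")
  both <- by_cell |>
    dplyr::group_by(.data$age_group, .data$disease) |>
    dplyr::summarise(sex = "both", n = sum(.data$n), .groups = "drop")
  wide <- dplyr::bind_rows(by_cell, both) |>
    tidyr::pivot_wider(names_from = "disease", values_from = "n",
                       values_fill = 0L)
  for (d in c("CD", "UC")) if (!d %in% names(wide)) wide[[d]] <- integer(0)
  wide |>
    dplyr::rename(cd = "CD", uc = "UC") |>
    dplyr::mutate(undefined = .data$uc == 0,
                  ratio = ifelse(.data$undefined, NA_real_,
                                 .data$cd / .data$uc)) |>
    dplyr::arrange(.data$sex, .data$age_group)
}
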