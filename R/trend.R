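#' Fit the categorical-year Poisson trend model
#'
#' Log-linear model of incident counts, `log E[count] = log(population) +
#' intercept + year effects (+ age-group effects when adjusting)`, with
#' calendar year a categorical factor and a chosen reference year. Fitting is
#' maximum likelihood via iteratively reweighted least squares
#' ([stats::glm()] with `family = poisson`, convergence tolerance `1e-12`,
#' up to 100 iterations); the covariance is the inverse observed information.
#' Cells with zero population are excluded from the likelihood with a
#' warning. Year levels whose total count is zero are reported as
#' non-estimable rather than crashing.
#'
#' @param cells tibble with columns `year`, `count`, `population` and, when
#'   `adjust_age = TRUE`, `age_group`.
#' @param reference_year the year whose effect is fixed at zero (default
#'   1996).
#' @param adjust_age include age group as an adjustment factor.
#' @return list with `fit` (the `glm` object), `years` (tibble:
#'   `target_year`, `coefficient`, `se`, `estimable`) and `reference_year`.
#' @export
fit_poisson_trend <- function(cells, reference_year = 1996L,
                              adjust_age = FALSE) {
  need <- c("year", "count", "population", if (adjust_age) "age_group")
  check_columns(cells, need, "model cells")
  if (any(cells$count < 0) || any(cells$count != round(cells$count))) {
    stop("counts must be non-negative integers")
  }
  if (!reference_year %in% cells$year) {
    stop("reference_year must be one of the design's year levels")
  }
  drop <- cells$population <= 0
  if (any(drop)) {
    warning(sprintf("excluding %d zero-population cell(s) from the likelihood",
                    sum(drop)))
    cells <- cells[!drop, , drop = FALSE]
  }
  d <- as_tibble(cells)
  d$year_f <- stats::relevel(factor(d$year), ref = as.character(reference_year))
  f <- if (adjust_age) {
    d$age_f <- factor(as.character(d$age_group))
    count ~ year_f + age_f
  } else {
    count ~ year_f
  }
  fit <- stats::glm(f, family = stats::poisson(), data = d,
                    offset = log(d$population),
                    control = stats::glm.control(epsilon = 1e-12, maxit = 100))
  if (!fit$converged) {
    stop("Poisson trend model did not converge within 100 IRLS iterations")
  }
  co <- summary(fit)$coefficients
  year_levels <- setdiff(levels(d$year_f), as.character(reference_year))
  zero_level <- as.vector(tapply(d$count, as.character(d$year),
                                 sum)[year_levels] == 0)
  terms <- paste0("year_f", year_levels)
  present <- terms %in% rownames(co)
  years <- tibble(
    target_year = as.integer(year_levels),
    coefficient = ifelse(present, co[terms, "Estimate"], NA_real_),
    se = ifelse(present, co[terms, "Std. Error"], NA_real_),
    estimable = present & !zero_level
  )
  years$coefficient[!years$estimable] <- NA_real_
  years$se[!years$estimable] <- NA_real_
  list(fit = fit, years = years, reference_year = as.integer(reference_year))
}

#' Percent change and Wald confidence interval from a log rate ratio
#'
#' Point estimate `100 * (exp(beta) - 1)` with the normal-theory interval
#' `100 * (exp(beta +/- z * se) - 1)`.
#'
#' @param coefficient log rate ratio(s).
#' @param se standard error(s) on the log scale (`>= 0`).
#' @param level confidence level (default 0.95).
#' @return tibble `percent_change`, `ci_low`, `ci_high`, `coefficient`, `se`.
#' @examples
#' percent_change(log(0.675), 0.1) # about -32.5%
#' @export
percent_change <- function(coefficient, se, level = 0.95) {
  if (any(se < 0, na.rm = TRUE)) stop("`se` must be non-negative")
  z <- stats::qnorm(1 - (1 - level) / 2)
  tibble(
    percent_change = 100 * (exp(coefficient) - 1),
    ci_low = 100 * (exp(coefficient - z * se) - 1),
    ci_high = 100 * (exp(coefficient + z * se) - 1),
    coefficient = coefficient,
    se = se
  )
}

#' Fit the full suite of stratified trend models
#'
#' One categorical-year Poisson model per disease (CD, UC, IBDU and the IBD
#' union) and sex level (female, male, both) for each age bin of the trend
#' grouping, plus an all-ages model per disease and sex level with age group
#' as an adjustment factor. Percent changes are reported for every non-
#' reference year level; the conventional one-number summary per stratum is
#' the final-year contrast against the reference year.
#'
#' @param cases case records from [ascertain_cases()].
#' @param registry person table.
#' @param population denominators (`year`, `age_group`, `sex`, `count`) on a
#'   grouping that nests inside `grouping` (e.g. the 10-year bins).
#' @param grouping trend [age_grouping()] (default `<20`/`20-29`/`30-39`/
#'   `40-49`/`50+`).
#' @param population_grouping the grouping of the `population` table.
#' @param reference_year reference level for the year factor.
#' @param years study years; defaults to those present in `population`.
#' @param diseases subset of `c("CD","UC","IBDU","IBD")`.
#' @return tibble: `disease`, `sex`, `age_group` (bin label or `"all"`),
#'   `adjusted`, `target_year`, `percent_change`, `ci_low`, `ci_high`,
#'   `coefficient`, `se`, `estimable`.
#' @export
run_trend_suite <- function(cases, registry, population,
                            grouping = trend_age_grouping(),
                            population_grouping = default_age_grouping(),
                            reference_year = 1996L, years = NULL,
                            diseases = ALL_DISEASES) {
  if (is.null(years)) years <- sort(unique(population$year))
  pop <- regroup_population(population, population_grouping, grouping) |>
    dplyr::mutate(age_group = as.character(.data$age_group))
  pop_both <- pop |>
    dplyr::group_by(.data$year, .data$age_group) |>
    dplyr::summarise(sex = "both", count = sum(.data$count), .groups = "drop")
  pop <- dplyr::bind_rows(pop, pop_both)

  cube <- tabulate_cases(cases, registry, grouping, years = years) |>
    dplyr::mutate(age_group = as.character(.data$age_group))
  cube_both <- cube |>
    dplyr::group_by(.data$year, .data$age_group, .data$disease) |>
    dplyr::summarise(sex = "both", n = sum(.data$n), .groups = "drop")
  cube <- dplyr::bind_rows(cube, cube_both)

  cells_all <- cube |>
    dplyr::inner_join(pop, by = c("year", "age_group", "sex")) |>
    dplyr::rename(count = "n", population = "count")

  strata <- tidyr::expand_grid(disease = diseases,
                               sex = c("female", "male", "both"),
                               age_group = c(grouping$labels, "all"))
  res <- lapply(seq_len(nrow(strata)), function(i) {
    st <- strata[i, ]
    adj <- st$age_group == "all"
    cells <- cells_all |>
      dplyr::filter(.data$disease == st$disease, .data$sex == st$sex)
    if (!adj) cells <- dplyr::filter(cells, .data$age_group == st$age_group)
    fit <- withCallingHandlers(
      fit_poisson_trend(cells, reference_year, adjust_age = adj),
      warning = function(w) invokeRestart("muffleWarning")
    )
    pc <- percent_change(fit$years$coefficient, fit$years$se)
    dplyr::bind_cols(
      st[rep(1, nrow(fit$years)), ],
      tibble(adjusted = adj, target_year = fit$years$target_year),
      pc, tibble(estimable = fit$years$estimable)
    )
  })
  dplyr::bind_rows(res)
}
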