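#' Default age distribution and incidence surface for the simulator
#'
#' `default_age_distribution()` returns weights over the 10-year reporting
#' bins loosely matching an older eastern-Canadian provincial age structure.
#' `default_incidence_surface()` returns per-100,000 person-year onset rates
#' by disease, age group and sex, bell-shaped with a peak in the 20-29 bin
#' (steeper for Crohn's disease, flatter for ulcerative colitis).
#' `incidence_surface()` builds a flat surface from scalar rates, convenient
#' for calibration and parameter-recovery experiments.
#'
#' @param cd,uc onset rates per 100,000 person-years applied to every age
#'   group and sex.
#' @param grouping an [age_grouping()] for the surface rows.
#' @return `default_age_distribution()`: named numeric weights summing to 1.
#'   The surfaces: tibbles with columns `disease`, `age_group`, `sex`, `rate`.
#' @export
default_age_distribution <- function() {
  g <- default_age_grouping()
  stats::setNames(c(0.10, 0.13, 0.13, 0.15, 0.16, 0.13, 0.10, 0.07, 0.03),
                  g$labels)
}

#' @rdname default_age_distribution
#' @export
incidence_surface <- function(cd, uc, grouping = default_age_grouping()) {
  tidyr::expand_grid(disease = c("CD", "UC"), age_group = grouping$labels,
                     sex = c("female", "male")) |>
    dplyr::mutate(rate = ifelse(.data$disease == "CD", cd, uc))
}

#' @rdname default_age_distribution
#' @export
default_incidence_surface <- function() {
  g <- default_age_grouping()
  cd <- c(2, 25, 45, 35, 25, 20, 12, 8, 4)
  uc <- c(1.5, 15, 30, 30, 28, 25, 18, 12, 6)
  dplyr::bind_rows(
    tidyr::expand_grid(sex = c("female", "male"),
                       tibble(disease = "CD", age_group = g$labels, rate = cd)),
    tidyr::expand_grid(sex = c("female", "male"),
                       tibble(disease = "UC", age_group = g$labels, rate = uc))
  ) |>
    dplyr::select("disease", "age_group", "sex", "rate")
}

#' Simulation configuration
#'
#' Validated parameter set for the synthetic-claims generator. The generator
#' emulates a provincial administrative database: a covered population with a
#' fixed age/sex structure, disease onsets with configurable baseline
#' incidence and a multiplicative calendar-year trend, a post-onset
#' care-contact process (Poisson physician claims, Bernoulli hospitalizations
#' per year), diagnostic-code noise that produces mixed CD/UC coding, an
#' ICD-9 to ICD-10 calendar cutover, and background non-IBD encounters.
#'
#' @param seed integer RNG seed; each generator stage derives its own seed
#'   from it, so every stage is reproducible in isolation.
#' @param n_persons number of covered persons.
#' @param calendar_span `c(first_year, last_year)` of the study period (rates
#'   are reported for these years; the trend exponent is relative to
#'   `first_year`).
#' @param washout_span `c(first_year, last_year)` of the pre-study run-in;
#'   encounters (and onsets) are generated from its first year onward.
#' @param age_distribution named weights over the 10-year age bins (age
#'   attained in `first_year`); must sum to 1.
#' @param sex_ratio proportion female in `[0, 1]`.
#' @param baseline_incidence tibble (`disease`, `age_group`, `sex`, `rate`)
#'   of onset rates per 100,000 person-years; see [incidence_surface()].
#' @param annual_trend named vector `c(CD = ..., UC = ...)` of multiplicative
#'   per-calendar-year factors on the onset hazard (0.97 = 3% annual decline).
#' @param claims_per_year_post_onset mean of the Poisson count of IBD-coded
#'   physician claims per year after onset.
#' @param hospitalization_prob_per_year per-year probability of an IBD-coded
#'   hospital discharge after onset.
#' @param code_noise_prob probability that an IBD encounter of a true-CD
#'   (true-UC) patient is coded with the opposite disease's code.
#' @param icd10_transition_year encounters before this calendar year carry
#'   ICD-9 codes, from it onward ICD-10.
#' @param background_encounter_rate mean non-IBD encounters per person-year.
#' @param record_end_year last calendar year with encounter records (default
#'   one year past the study span, so cases with onset late in the final
#'   study year can still accumulate the contacts that satisfy the gate,
#'   mirroring a records span that outlasts the reporting span).
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_persons = 50000L,
                       calendar_span = c(1996L, 2009L),
                       washout_span = c(1991L, 1995L),
                       age_distribution = default_age_distribution(),
                       sex_ratio = 0.51,
                       baseline_incidence = default_incidence_surface(),
                       annual_trend = c(CD = 0.97, UC = 0.98),
                       claims_per_year_post_onset = 4,
                       hospitalization_prob_per_year = 0.2,
                       code_noise_prob = 0.05,
                       icd10_transition_year = 2001L,
                       background_encounter_rate = 1,
                       record_end_year = NULL) {
  cfg <- list(seed = as.integer(seed), n_persons = as.integer(n_persons),
              calendar_span = as.integer(calendar_span),
              washout_span = as.integer(washout_span),
              age_distribution = age_distribution, sex_ratio = sex_ratio,
              baseline_incidence = as_tibble(baseline_incidence),
              annual_trend = annual_trend,
              claims_per_year_post_onset = claims_per_year_post_onset,
              hospitalization_prob_per_year = hospitalization_prob_per_year,
              code_noise_prob = code_noise_prob,
              icd10_transition_year = as.integer(icd10_transition_year),
              background_encounter_rate = background_encounter_rate,
              record_end_year = as.integer(record_end_year %||%
                                             (calendar_span[2] + 1L)))

  if (is.na(cfg$seed)) stop_config("seed", "must be an integer")
  if (is.na(cfg$n_persons) || cfg$n_persons < 0) {
    stop_config("n_persons", "must be a non-negative integer")
  }
  if (length(cfg$calendar_span) != 2 ||
      cfg$calendar_span[1] > cfg$calendar_span[2]) {
    stop_config("calendar_span", "must be c(first_year, last_year) with first <= last")
  }
  if (length(cfg$washout_span) != 2 ||
      cfg$washout_span[1] > cfg$washout_span[2]) {
    stop_config("washout_span", "must be c(first_year, last_year) with first <= last")
  }
  if (cfg$washout_span[1] > cfg$calendar_span[1]) {
    stop_config("washout_span", "must precede or overlap the calendar span start")
  }
  g <- default_age_grouping()
  if (!setequal(names(cfg$age_distribution), g$labels)) {
    stop_config("age_distribution", "must be named by the 10-year age bins")
  }
  cfg$age_distribution <- cfg$age_distribution[g$labels]
  if (any(cfg$age_distribution < 0) ||
      abs(sum(cfg$age_distribution) - 1) > 1e-9) {
    stop_config("age_distribution", "weights must be non-negative and sum to 1")
  }
  for (f in c("sex_ratio", "code_noise_prob", "hospitalization_prob_per_year")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop_config(f, "must be in [0, 1]")
  }
  for (f in c("claims_per_year_post_onset", "background_encounter_rate")) {
    if (cfg[[f]] < 0) stop_config(f, "must be non-negative")
  }
  check_columns(cfg$baseline_incidence,
                c("disease", "age_group", "sex", "rate"), "baseline_incidence")
  if (any(cfg$baseline_incidence$rate < 0)) {
    stop_config("baseline_incidence", "rates must be non-negative")
  }
  if (!all(c("CD", "UC") %in% names(cfg$annual_trend)) ||
      any(cfg$annual_trend <= 0)) {
    stop_config("annual_trend", "must be positive and named CD and UC")
  }
  if (is.na(cfg$record_end_year) ||
      cfg$record_end_year < cfg$calendar_span[2]) {
    stop_config("record_end_year", "must be at or after the calendar span end")
  }
  structure(cfg, class = "sim_config")
}

# single-year-of-age sampling table: bin weights spread uniformly inside each
# bin (80+ spread over 80-94), plus cohorts born during the study drawn with
# the youngest bin's per-year density so the <10 denominator stays populated.
age_at_start_probs <- function(cfg) {
  g <- default_age_grouping()
  w <- cfg$age_distribution
  upper <- ifelse(is.infinite(g$upper), 95, g$upper)
  width <- upper - g$breaks
  ages <- integer(0); dens <- numeric(0)
  for (i in seq_along(g$breaks)) {
    a <- seq(g$breaks[i], upper[i] - 1)
    ages <- c(ages, a)
    dens <- c(dens, rep(w[i] / width[i], length(a)))
  }
  span_years <- cfg$calendar_span[2] - cfg$calendar_span[1]
  if (span_years > 0) {
    born_later <- seq(-span_years, -1)
    ages <- c(born_later, ages)
    dens <- c(rep(w[1] / width[1], span_years), dens)
  }
  list(ages = ages, probs = dens / sum(dens))
}

#' Simulate a covered-person registry and its population denominators
#'
#' Draws `n_persons` with sex and birth dates per the configuration. Age
#' weights describe the age attained in the first study year; additional
#' cohorts born during the study are drawn at the youngest bin's per-year
#' density so every age bin keeps a denominator across the span. Coverage
#' runs from the later of birth and the washout start through the end of the
#' record span (no deaths or migration). The population table counts each
#' person in each covered study year at the age attained that year
#' (`year - birth_year`).
#'
#' @param config a [sim_config()].
#' @return list with `registry` (tibble: `person_id`, `sex`, `birth_date`,
#'   `cover_start`, `cover_end`) and `population` (tibble: `year`,
#'   `age_group`, `sex`, `count`, complete and zero-filled over the study
#'   span).
#' @export
simulate_registry <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  g <- default_age_grouping()
  first <- config$calendar_span[1]; last <- config$calendar_span[2]
  years <- seq(first, last)
  grid <- tidyr::expand_grid(year = years,
                             age_group = factor(g$labels, levels = g$labels),
                             sex = c("female", "male"))
  n <- config$n_persons
  if (n == 0) {
    registry <- tibble(person_id = character(0), sex = character(0),
                       birth_date = as.Date(character(0)),
                       cover_start = as.Date(character(0)),
                       cover_end = as.Date(character(0)))
    return(list(registry = registry,
                population = dplyr::mutate(grid, count = 0L)))
  }

  sex <- ifelse(stats::runif(n) < config$sex_ratio, "female", "male")
  tab <- age_at_start_probs(config)
  age0 <- sample(tab$ages, n, replace = TRUE, prob = tab$probs)
  birth_year <- first - age0
  birth_date <- jan1(birth_year) + floor(stats::runif(n, 0, 365))
  cover_start <- pmax(birth_date, jan1(config$washout_span[1]))
  registry <- tibble(
    person_id = sprintf("P%07d", seq_len(n)),
    sex = sex, birth_date = birth_date,
    cover_start = cover_start, cover_end = dec31(config$record_end_year)
  )

  pop <- lapply(years, function(y) {
    alive <- birth_year <= y
    if (!any(alive)) return(NULL)
    tibble(year = y,
           age_group = assign_age_group(y - birth_year[alive], g),
           sex = sex[alive]) |>
      dplyr::count(.data$year, .data$age_group, .data$sex, name = "count")
  })
  population <- dplyr::bind_rows(pop) |>
    dplyr::right_join(grid, by = c("year", "age_group", "sex")) |>
    dplyr::mutate(count = ifelse(is.na(.data$count), 0L, .data$count)) |>
    dplyr::arrange(.data$year, .data$age_group, .data$sex)

  list(registry = registry, population = population)
}

#' Simulate disease onsets with a calendar-year incidence trend
#'
#' Each disease-free person acquires disease `d` in calendar year `y` with
#' hazard `rate[d, age_group, sex] / 100000 * annual_trend[d]^(y -
#' first_study_year)`; at most one disease per person (competing draws on one
#' uniform per person-year); onset dates are uniform within the onset year.
#' Onsets are drawn from the washout start through the last study year, so
#' prevalent cases exist for the washout stage to remove.
#'
#' @param registry the registry tibble from [simulate_registry()].
#' @param config a [sim_config()].
#' @return ground-truth tibble of diseased persons only: `person_id`,
#'   `true_disease` (`"CD"`/`"UC"`), `true_onset_date`.
#' @export
simulate_disease_onsets <- function(registry, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  empty <- tibble(person_id = character(0), true_disease = character(0),
                  true_onset_date = as.Date(character(0)))
  n <- nrow(registry)
  if (n == 0) return(empty)

  g <- default_age_grouping()
  surf <- config$baseline_incidence
  rate_of <- function(disease) {
    m <- matrix(0, nrow = length(g$labels), ncol = 2,
                dimnames = list(g$labels, c("female", "male")))
    s <- surf[surf$disease == disease, ]
    m[cbind(as.character(s$age_group), s$sex)] <- s$rate
    m
  }
  m_cd <- rate_of("CD"); m_uc <- rate_of("UC")

  birth_year <- year_of(registry$birth_date)
  sex_col <- ifelse(registry$sex == "female", 1L, 2L)
  first_study <- config$calendar_span[1]
  years <- seq(config$washout_span[1], config$calendar_span[2])

  disease <- rep(NA_character_, n)
  onset <- rep(as.Date(NA), n)
  for (y in years) {
    at_risk <- which(is.na(disease) & birth_year <= y)
    if (length(at_risk) == 0) next
    grp <- findInterval(y - birth_year[at_risk], g$breaks)
    p_cd <- m_cd[cbind(grp, sex_col[at_risk])] / 1e5 *
      config$annual_trend[["CD"]]^(y - first_study)
    p_uc <- m_uc[cbind(grp, sex_col[at_risk])] / 1e5 *
      config$annual_trend[["UC"]]^(y - first_study)
    u <- stats::runif(length(at_risk))
    hit_cd <- u < p_cd
    hit_uc <- !hit_cd & u < p_cd + p_uc
    hit <- hit_cd | hit_uc
    if (!any(hit)) next
    idx <- at_risk[hit]
    disease[idx] <- ifelse(hit_cd[hit], "CD", "UC")
    win_start <- pmax(jan1(y), registry$birth_date[idx])
    win_len <- as.numeric(dec31(y) - win_start) + 1
    onset[idx] <- win_start + floor(stats::runif(length(idx)) * win_len)
  }
  keep <- !is.na(disease)
  if (!any(keep)) return(empty)
  tibble(person_id = registry$person_id[keep], true_disease = disease[keep],
         true_onset_date = onset[keep])
}

disease_code <- function(disease, icd_version) {
  ifelse(icd_version == 9L,
         ifelse(disease == "CD", "555.9", "556.9"),
         ifelse(disease == "CD", "K50.9", "K51.9"))
}

background_codes <- function(icd_version) {
  icd9 <- c("250.0", "401.9", "786.5", "V70.0")
  icd10 <- c("E11.9", "I10", "R05", "Z00.0")
  ifelse(icd_version == 9L,
         icd9[sample.int(4L, length(icd_version), replace = TRUE)],
         icd10[sample.int(4L, length(icd_version), replace = TRUE)])
}

#' Simulate ICD-coded encounter streams
#'
#' Post-onset persons emit physician claims (Poisson count per year, mean
#' `claims_per_year_post_onset`, prorated in the onset year) and hospital
#' discharges (Bernoulli per year) carrying their true disease's ICD code,
#' flipped to the other disease's code with probability `code_noise_prob`.
#' All persons emit background encounters with non-IBD codes at
#' `background_encounter_rate` per covered person-year. Encounters before
#' `icd10_transition_year` carry ICD-9 codes, from it onward ICD-10. Every
#' encounter falls inside its person's coverage interval.
#'
#' @param registry registry tibble from [simulate_registry()].
#' @param truths ground-truth tibble from [simulate_disease_onsets()]; must
#'   reference only registry persons.
#' @param config a [sim_config()].
#' @return encounter tibble (`person_id`, `date`, `source`, `icd_version`,
#'   `code`) sorted by person and date.
#' @export
simulate_encounters <- function(registry, truths, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  empty <- tibble(person_id = character(0), date = as.Date(character(0)),
                  source = character(0), icd_version = integer(0),
                  code = character(0))
  if (nrow(registry) == 0) return(empty)
  if (!all(truths$person_id %in% registry$person_id)) {
    stop("data error: truths reference persons missing from the registry")
  }
  last <- config$record_end_year
  parts <- list()

  if (nrow(truths) > 0) {
    tt <- dplyr::inner_join(truths, registry, by = "person_id")
    onset_year <- year_of(tt$true_onset_date)
    reps <- last - onset_year + 1L
    py <- tibble(
      person_id = rep(tt$person_id, reps),
      true_disease = rep(tt$true_disease, reps),
      onset = rep(tt$true_onset_date, reps),
      year = unlist(lapply(seq_len(nrow(tt)),
                           function(i) seq(onset_year[i], last)))
    )
    win_start <- pmax(jan1(py$year), py$onset)
    win_len <- as.numeric(dec31(py$year) - win_start) + 1
    frac <- win_len / 365
    n_claims <- stats::rpois(nrow(py), config$claims_per_year_post_onset * frac)
    hosp <- stats::rbinom(nrow(py), 1L,
                          pmin(1, config$hospitalization_prob_per_year * frac))

    emit <- function(counts, src) {
      m <- sum(counts)
      if (m == 0) return(NULL)
      ridx <- rep(seq_len(nrow(py)), counts)
      date <- win_start[ridx] +
        floor(stats::runif(m) * win_len[ridx])
      iv <- ifelse(year_of(date) < config$icd10_transition_year, 9L, 10L)
      true_d <- py$true_disease[ridx]
      flip <- stats::runif(m) < config$code_noise_prob
      obs_d <- ifelse(flip, ifelse(true_d == "CD", "UC", "CD"), true_d)
      tibble(person_id = py$person_id[ridx], date = date, source = src,
             icd_version = iv, code = disease_code(obs_d, iv))
    }
    parts$claims <- emit(n_claims, "claim")
    parts$discharges <- emit(hosp, "discharge")
  }

  if (config$background_encounter_rate > 0) {
    birth_year <- year_of(registry$birth_date)
    cov_start_year <- year_of(registry$cover_start)
    reps <- pmax(0L, last - cov_start_year + 1L)
    keep <- which(reps > 0)
    bg <- tibble(
      person_id = rep(registry$person_id[keep], reps[keep]),
      cover_start = rep(registry$cover_start[keep], reps[keep]),
      year = unlist(lapply(keep, function(i) seq(cov_start_year[i], last)))
    )
    win_start <- pmax(jan1(bg$year), bg$cover_start)
    win_len <- as.numeric(dec31(bg$year) - win_start) + 1
    n_bg <- stats::rpois(nrow(bg), config$background_encounter_rate *
                           win_len / 365)
    m <- sum(n_bg)
    if (m > 0) {
      ridx <- rep(seq_len(nrow(bg)), n_bg)
      date <- win_start[ridx] + floor(stats::runif(m) * win_len[ridx])
      iv <- ifelse(year_of(date) < config$icd10_transition_year, 9L, 10L)
      parts$background <- tibble(person_id = bg$person_id[ridx], date = date,
                                 source = "claim", icd_version = iv,
                                 code = background_codes(iv))
    }
  }

  out <- dplyr::bind_rows(parts)
  if (nrow(out) == 0) return(empty)
  dplyr::arrange(out, .data$person_id, .data$date)
}

#' Simulate a full synthetic cohort
#'
#' Convenience wrapper running [simulate_registry()],
#' [simulate_disease_onsets()] and [simulate_encounters()] in sequence.
#'
#' @param config a [sim_config()].
#' @return list with `registry`, `population`, `truths`, `encounters`.
#' @export
simulate_cohort <- function(config) {
  reg <- simulate_registry(config)
  truths <- simulate_disease_onsets(reg$registry, config)
  encounters <- simulate_encounters(reg$registry, truths, config)
  list(registry = reg$registry, population = reg$population,
       truths = truths, encounters = encounters)
}
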