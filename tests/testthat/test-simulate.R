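test_that("configuration validation names the offending field", {
  expect_error(sim_config(sex_ratio = 1.2), "sex_ratio")
  expect_error(sim_config(code_noise_prob = -0.1), "code_noise_prob")
  expect_error(sim_config(calendar_span = c(2009, 1996)), "calendar_span")
  expect_error(sim_config(washout_span = c(1997, 1998)), "washout_span")
  expect_error(sim_config(n_persons = -1), "n_persons")
  bad_dist <- default_age_distribution(); bad_dist[1] <- bad_dist[1] + 0.5
  expect_error(sim_config(age_distribution = bad_dist), "age_distribution")
  expect_error(sim_config(annual_trend = c(CD = 0.97)), "annual_trend")
})

test_that("an empty cohort yields empty tables, not errors", {
  cfg <- sim_config(seed = 1, n_persons = 0)
  coh <- simulate_cohort(cfg)
  expect_equal(nrow(coh$registry), 0L)
  expect_equal(nrow(coh$truths), 0L)
  expect_equal(nrow(coh$encounters), 0L)
  expect_true(all(coh$population$count == 0))
  # population grid is still complete
  expect_equal(nrow(coh$population), 14 * 9 * 2)
})

test_that("identical configs give byte-identical cohorts", {
  cfg <- sim_config(seed = 5, n_persons = 2000)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  # a different seed changes the draw
  c_ <- simulate_cohort(sim_config(seed = 6, n_persons = 2000))
  expect_false(identical(a$encounters, c_$encounters))
})

test_that("degenerate probabilities behave as stated", {
  all_f <- simulate_registry(sim_config(seed = 2, n_persons = 500,
                                        sex_ratio = 1))
  expect_true(all(all_f$registry$sex == "female"))
  no_disease <- simulate_cohort(
    sim_config(seed = 2, n_persons = 500,
               baseline_incidence = incidence_surface(cd = 0, uc = 0))
  )
  expect_equal(nrow(no_disease$truths), 0L)
  silent <- simulate_cohort(
    sim_config(seed = 2, n_persons = 200,
               baseline_incidence = incidence_surface(cd = 0, uc = 0),
               background_encounter_rate = 0)
  )
  expect_equal(nrow(silent$encounters), 0L)
})

test_that("population table counts every person alive in each study year", {
  cfg <- sim_config(seed = 8, n_persons = 3000)
  reg <- simulate_registry(cfg)
  by <- as.integer(format(reg$registry$birth_date, "%Y"))
  for (y in c(1996L, 2003L, 2009L)) {
    expect_equal(sum(reg$population$count[reg$population$year == y]),
                 sum(by <= y))
  }
  # every age bin retains a denominator across the span (births continue)
  final <- reg$population[reg$population$year == 2009, ]
  expect_true(all(tapply(final$count, final$age_group, sum) > 0))
})

test_that("encounters stay inside coverage and respect the ICD cutover", {
  cfg <- sim_config(seed = 9, n_persons = 3000,
                    baseline_incidence = incidence_surface(cd = 100, uc = 100),
                    background_encounter_rate = 0.5)
  coh <- simulate_cohort(cfg)
  enc <- dplyr::inner_join(coh$encounters, coh$registry, by = "person_id")
  expect_true(all(enc$date >= enc$cover_start))
  expect_true(all(enc$date >= enc$birth_date))
  expect_true(all(enc$date <= enc$cover_end))
  yr <- as.integer(format(enc$date, "%Y"))
  expect_true(all(enc$icd_version[yr < 2001] == 9L))
  expect_true(all(enc$icd_version[yr >= 2001] == 10L))
  # noiseless true-CD persons only ever carry CD codes
  cfg0 <- sim_config(seed = 9, n_persons = 3000,
                     baseline_incidence = incidence_surface(cd = 100, uc = 0),
                     code_noise_prob = 0, background_encounter_rate = 0)
  coh0 <- simulate_cohort(cfg0)
  expect_true(all(map_code(coh0$encounters$code,
                           coh0$encounters$icd_version) == "CD"))
})

test_that("onsets only strike registered, alive persons at most once", {
  cfg <- sim_config(seed = 10, n_persons = 5000,
                    baseline_incidence = incidence_surface(cd = 200, uc = 200))
  coh <- simulate_cohort(cfg)
  expect_false(any(duplicated(coh$truths$person_id)))
  t <- dplyr::inner_join(coh$truths, coh$registry, by = "person_id")
  expect_true(all(t$true_onset_date >= t$birth_date))
  yr <- as.integer(format(t$true_onset_date, "%Y"))
  expect_true(all(yr >= 1991 & yr <= 2009))
})

test_that("empirical onset rate matches the configured incidence", {
  # flat 40/100k, no trend; ~100k person-years of risk
  cfg <- sim_config(seed = 77, n_persons = 8000,
                    baseline_incidence = incidence_surface(cd = 40, uc = 0),
                    annual_trend = c(CD = 1, UC = 1),
                    background_encounter_rate = 0)
  reg <- simulate_registry(cfg)
  truths <- simulate_disease_onsets(reg$registry, cfg)
  by <- as.integer(format(reg$registry$birth_date, "%Y"))
  person_years <- sum(vapply(1991:2009, function(y) sum(by <= y), numeric(1)))
  lambda <- person_years * 40 / 1e5
  expect_lt(abs(nrow(truths) - lambda), 3 * sqrt(lambda))
})
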