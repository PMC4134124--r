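test_that("saturated year-only fits reproduce empirical rate ratios", {
  cells <- tibble::tibble(year = c(1996, 2009), count = c(27, 18),
                          population = c(50000, 50000))
  fit <- fit_poisson_trend(cells, reference_year = 1996)
  expect_equal(exp(fit$years$coefficient), 18 / 27, tolerance = 1e-8)
  # random saturated designs: fitted rate = observed rate in every cell
  set.seed(21)
  for (i in 1:20) {
    k <- sample(3:8, 1)
    cells <- tibble::tibble(year = 1996 + seq_len(k) - 1,
                            count = stats::rpois(k, 40) + 1L,
                            population = round(stats::runif(k, 2e4, 9e4)))
    fit <- fit_poisson_trend(cells, reference_year = 1996)
    obs_rr <- (cells$count / cells$population)[-1] /
      (cells$count[1] / cells$population[1])
    expect_equal(exp(fit$years$coefficient), obs_rr, tolerance = 1e-8)
  }
})

test_that("equal counts and offsets give zero year effects", {
  cells <- tibble::tibble(year = 1996:2000, count = 25, population = 40000)
  fit <- fit_poisson_trend(cells, reference_year = 1996)
  expect_equal(fit$years$coefficient, rep(0, 4), tolerance = 1e-10)
})

test_that("scaling every offset shifts only the intercept", {
  cells <- tibble::tibble(year = 1996:1999, count = c(30, 24, 28, 20),
                          population = c(4, 5, 6, 4) * 1e4)
  f1 <- fit_poisson_trend(cells, 1996)
  f2 <- fit_poisson_trend(dplyr::mutate(cells, population = population * 7), 1996)
  expect_equal(f1$years$coefficient, f2$years$coefficient, tolerance = 1e-8)
  expect_equal(stats::coef(f2$fit)[["(Intercept)"]],
               stats::coef(f1$fit)[["(Intercept)"]] - log(7), tolerance = 1e-8)
})

test_that("zero-population cells are excluded with a warning", {
  cells <- tibble::tibble(year = 1996:1999, count = c(30, 24, 0, 20),
                          population = c(4e4, 5e4, 0, 4e4))
  expect_warning(fit <- fit_poisson_trend(cells, 1996), "zero-population")
  # the 1998 level leaves the design entirely
  expect_setequal(fit$years$target_year, c(1997L, 1999L))
})

test_that("all-zero year levels are non-estimable, not a crash", {
  cells <- tibble::tibble(year = 1996:1999, count = c(30, 0, 28, 20),
                          population = 4e4)
  fit <- fit_poisson_trend(cells, 1996)
  row <- fit$years[fit$years$target_year == 1997, ]
  expect_false(row$estimable)
  expect_true(is.na(row$coefficient))
  expect_true(all(fit$years$estimable[fit$years$target_year != 1997]))
})

test_that("percent change is the exponentiated contrast with Wald limits", {
  expect_equal(percent_change(0, 0)$percent_change, 0)
  expect_equal(percent_change(0, 0)$ci_low, 0)
  expect_equal(percent_change(log(0.675), 0.1)$percent_change, -32.5)
  # independent arithmetic oracle
  z <- stats::qnorm(0.975)
  pc <- percent_change(-0.2, 0.1)
  expect_equal(pc$percent_change, 100 * (exp(-0.2) - 1))
  expect_equal(pc$ci_low, 100 * (exp(-0.2 - z * 0.1) - 1))
  expect_equal(pc$ci_high, 100 * (exp(-0.2 + z * 0.1) - 1))
  expect_true(pc$ci_low <= pc$percent_change &
                pc$percent_change <= pc$ci_high)
  expect_error(percent_change(0, -1), "non-negative")
})

test_that("Wald estimates land within 3 SEs of truth at large counts", {
  # Monte-Carlo check of estimator calibration on a known log-linear model
  set.seed(61)
  beta <- log(0.8)
  ok <- 0L
  for (r in 1:50) {
    pop <- 5e5
    counts <- stats::rpois(2, c(pop * 30e-5, pop * 30e-5 * exp(beta)))
    if (any(counts == 0)) next
    cells <- tibble::tibble(year = c(1996, 2009), count = counts,
                            population = pop)
    fit <- fit_poisson_trend(cells, 1996)
    ok <- ok + as.integer(
      abs(fit$years$coefficient - beta) <= 3 * fit$years$se
    )
  }
  expect_gte(ok, 49L)
})

test_that("the stratified suite covers every stratum and the IBD union", {
  cfg <- sim_config(seed = 41, n_persons = 10000,
                    baseline_incidence = incidence_surface(cd = 120, uc = 120),
                    annual_trend = c(CD = 1, UC = 1),
                    background_encounter_rate = 0)
  coh <- simulate_cohort(cfg)
  cases <- ascertain_cases(coh$registry, coh$encounters)
  tr <- run_trend_suite(cases, coh$registry, coh$population)
  expect_setequal(unique(tr$disease), c("CD", "UC", "IBDU", "IBD"))
  expect_setequal(unique(tr$sex), c("female", "male", "both"))
  expect_setequal(unique(tr$age_group),
                  c(trend_age_grouping()$labels, "all"))
  expect_setequal(unique(tr$target_year), 1997:2009)
  expect_true(all(tr$adjusted == (tr$age_group == "all")))
  # IBD estimates equal a fit on the summed CD+UC+IBDU counts: recompute one
  cube <- tabulate_cases(cases, coh$registry, trend_age_grouping(),
                         years = 1996:2009)
  pop <- regroup_population(coh$population, default_age_grouping(),
                            trend_age_grouping())
  cells <- cube |>
    dplyr::filter(disease == "IBD") |>
    dplyr::group_by(year, age_group) |>
    dplyr::summarise(count = sum(n), .groups = "drop") |>
    dplyr::inner_join(
      dplyr::summarise(dplyr::group_by(pop, year, age_group),
                       population = sum(count), .groups = "drop"),
      by = c("year", "age_group")
    )
  ref <- fit_poisson_trend(cells, 1996, adjust_age = TRUE)
  got <- tr[tr$disease == "IBD" & tr$sex == "both" & tr$age_group == "all", ]
  expect_equal(got$coefficient[order(got$target_year)],
               ref$years$coefficient[order(ref$years$target_year)],
               tolerance = 1e-10)
})

test_that("a flat-rate cohort yields null percent changes within the CIs", {
  cfg <- sim_config(seed = 43, n_persons = 30000,
                    baseline_incidence = incidence_surface(cd = 100, uc = 0),
                    annual_trend = c(CD = 1, UC = 1), code_noise_prob = 0,
                    background_encounter_rate = 0)
  coh <- simulate_cohort(cfg)
  cases <- ascertain_cases(coh$registry, coh$encounters)
  tr <- run_trend_suite(cases, coh$registry, coh$population, diseases = "CD")
  row <- tr[tr$sex == "both" & tr$age_group == "all" & tr$target_year == 2009, ]
  expect_true(row$ci_low <= 0 & 0 <= row$ci_high)
})
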