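fake_registry <- function(n, sexes, birth_years) {
  tibble::tibble(person_id = sprintf("P%04d", seq_len(n)), sex = sexes,
                 birth_date = as.Date(sprintf("%d-06-01", birth_years)),
                 cover_start = as.Date("1991-01-01"),
                 cover_end = as.Date("2010-12-31"))
}

fake_cases <- function(registry, years, categories) {
  tibble::tibble(person_id = registry$person_id, diagnosis_year = years,
                 diagnosis_date = as.Date(sprintf("%d-03-01", years)),
                 score = 4L, category = categories, n_claims = 4L,
                 n_discharges = 0L)
}

test_that("crude rates are cases per 100,000 with flagged empty cells", {
  expect_equal(as.numeric(crude_rate(23, 46000)), 50)
  expect_equal(as.numeric(crude_rate(0, 1234)), 0)
  expect_equal(as.numeric(crude_rate(27, 98550)), 27.39726, tolerance = 1e-6)
  z <- crude_rate(c(0, 5), c(0, 1000))
  expect_equal(as.numeric(z), c(0, 500))
  expect_equal(attr(z, "zero_denominator"), c(TRUE, FALSE))
  expect_error(crude_rate(1, 0), "undefined")
})

test_that("direct standardization is the weighted mean of age-specific rates", {
  std <- tibble::tibble(age_group = c("a", "b"), weight = c(0.5, 0.5))
  expect_equal(age_standardize(c(a = 10, b = 30), std), 20)
  # constant rates pass through untouched (weights sum to one)
  expect_equal(age_standardize(c(a = 7.3, b = 7.3), std), 7.3)
  # independent dot-product oracle on random inputs
  set.seed(12)
  for (i in 1:25) {
    k <- sample(3:9, 1)
    w <- stats::runif(k); w <- w / sum(w)
    r <- stats::runif(k, 0, 100)
    names(w) <- names(r) <- paste0("g", seq_len(k))
    got <- age_standardize(r, w)
    expect_equal(got, sum(w * r), tolerance = 1e-12)
    expect_gte(got, min(r) - 1e-12)
    expect_lte(got, max(r) + 1e-12)
  }
})

test_that("standardization errors on bad weights or missing coverage", {
  expect_error(age_standardize(c(a = 1), c(a = 0.7, b = 0.7)), "sum to 1")
  expect_error(
    age_standardize(tibble::tibble(age_group = "a", rate = 5),
                    tibble::tibble(age_group = c("a", "b"),
                                   weight = c(0.5, 0.5))),
    "coverage"
  )
})

test_that("the bundled standard sums to one over the 10-year bins", {
  std <- canada_2006_standard()
  expect_setequal(std$age_group, default_age_grouping()$labels)
  expect_equal(sum(std$weight), 1, tolerance = 1e-12)
  expect_true(all(std$weight > 0))
})

test_that("case tabulation conserves counts and zero-fills the cube", {
  reg <- fake_registry(6, rep(c("female", "male"), 3),
                       c(1980, 1950, 1996, 1970, 1940, 1985))
  cases <- fake_cases(reg, c(1997, 1997, 2005, 2001, 2009, 1996),
                      c("CD", "UC", "IBDU", "CD", "UC", "CD"))
  cube <- tabulate_cases(cases, reg, years = 1996:2009, add_ibd = FALSE)
  expect_equal(sum(cube$n), nrow(cases))
  expect_equal(nrow(cube), 14 * 9 * 2 * 3)
  # brute-force recount of one cell
  expect_equal(
    cube$n[cube$year == 1997 & cube$age_group == "10-19" &
             cube$sex == "female" & cube$disease == "CD"],
    sum(cases$diagnosis_year == 1997 & cases$category == "CD" &
          reg$sex == "female" &
          (1997 - as.integer(format(reg$birth_date, "%Y"))) %in% 10:19)
  )
  empty <- tabulate_cases(cases[0, ], reg, years = 1996:2009)
  expect_true(all(empty$n == 0))
})

test_that("rate tables standardize correctly and scale-invariantly", {
  set.seed(31)
  cfg <- sim_config(seed = 31, n_persons = 8000,
                    baseline_incidence = incidence_surface(cd = 80, uc = 60),
                    background_encounter_rate = 0)
  coh <- simulate_cohort(cfg)
  cases <- ascertain_cases(coh$registry, coh$encounters)
  rt <- build_rate_tables(cases, coh$registry, coh$population)
  # IBD cases are the sum of the components in every cell
  wide <- tidyr::pivot_wider(
    dplyr::select(rt, "year", "age_group", "sex", "disease", "cases"),
    names_from = "disease", values_from = "cases"
  )
  expect_equal(wide$IBD, wide$CD + wide$UC + wide$IBDU)
  # ASR rows are the dot product of crude rates with the standard weights
  std <- canada_2006_standard()
  crude <- rt[rt$rate_type == "crude" & rt$year == 2000 &
                rt$sex == "both" & rt$disease == "CD", ]
  asr <- rt$rate[rt$rate_type == "asr" & rt$year == 2000 &
                   rt$sex == "both" & rt$disease == "CD"]
  expect_equal(asr, sum(std$weight[match(crude$age_group, std$age_group)] *
                          crude$rate), tolerance = 1e-12)
  # doubling cases and population leaves every rate unchanged
  reg2 <- coh$registry
  reg2b <- dplyr::mutate(reg2, person_id = paste0(person_id, "b"))
  cases2 <- dplyr::bind_rows(cases,
                             dplyr::mutate(cases, person_id = paste0(person_id, "b")))
  pop2 <- dplyr::mutate(coh$population, count = count * 2L)
  rt2 <- build_rate_tables(cases2, dplyr::bind_rows(reg2, reg2b), pop2)
  expect_equal(rt2$rate, rt$rate, tolerance = 1e-12)
})

test_that("a single age bin makes the ASR equal the crude rate", {
  g1 <- age_grouping(0, labels = "all_ages")
  reg <- fake_registry(4, rep("female", 4), c(1950, 1960, 1970, 1980))
  cases <- fake_cases(reg, c(1996, 1996, 1997, 1998), rep("CD", 4))
  pop <- tidyr::expand_grid(year = 1996:1998, age_group = "all_ages",
                            sex = c("female", "male"), count = 50000)
  std1 <- tibble::tibble(age_group = "all_ages", weight = 1)
  rt <- build_rate_tables(cases, reg, pop, std = std1, grouping = g1,
                          years = 1996:1998)
  both <- rt[rt$sex == "both" & rt$disease == "CD", ]
  expect_equal(both$rate[both$rate_type == "asr"],
               both$rate[both$rate_type == "crude"])
})

test_that("CD:UC ratios divide incident counts and flag empty denominators", {
  reg <- fake_registry(6, c(rep("female", 5), "male"),
                       c(rep(1975, 5), 1975))
  cases <- fake_cases(reg, rep(2000, 6),
                      c("CD", "CD", "CD", "UC", "UC", "CD"))
  r <- cd_uc_ratio_by_age(cases, reg)
  fem <- r[r$sex == "female" & r$age_group == "20-29", ]
  expect_equal(fem$ratio, 3 / 2)
  male <- r[r$sex == "male" & r$age_group == "20-29", ]
  expect_true(male$undefined)
  expect_true(is.na(male$ratio))
  both <- r[r$sex == "both" & r$age_group == "20-29", ]
  expect_equal(both$ratio, 4 / 2)
})
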