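test_that("generators are deterministic under a fixed seed", {
  g1 <- generate_survey_points(survey_gen_config(seed = 7))
  g2 <- generate_survey_points(survey_gen_config(seed = 7))
  expect_identical(g1$points, g2$points)
  expect_identical(g1$covariates, g2$covariates)

  o1 <- generate_observation_study(obs_gen_config(seed = 7))
  o2 <- generate_observation_study(obs_gen_config(seed = 7))
  expect_identical(o1$records, o2$records)

  m1 <- generate_meta_studies(meta_gen_config(seed = 7))
  m2 <- generate_meta_studies(meta_gen_config(seed = 7))
  expect_identical(m1$studies, m2$studies)

  g3 <- generate_survey_points(survey_gen_config(seed = 8))
  expect_false(identical(g1$points, g3$points))
})

test_that("noise-free survey points equal the fixed-part inverse logit", {
  g <- generate_survey_points(noise_free_config(seed = 3))
  joined <- dplyr::inner_join(g$points, g$covariates, by = "country_id")
  expected <- purrr::pmap_dbl(
    joined[c("stratum", "who_region", "income_group", "year")],
    \(stratum, who_region, income_group, year)
      true_presence(g$truth, stratum, who_region, income_group, year))
  expect_equal(joined$proportion, expected, tolerance = 1e-12)
})

test_that("survey generator reproduces the sparse data pattern", {
  g <- generate_survey_points(survey_gen_config(seed = 11))
  n_countries <- nrow(g$covariates)
  expect_identical(n_countries, 194L)
  with_points <- dplyr::n_distinct(g$points$country_id)
  frac_zero <- 1 - with_points / n_countries
  # the emulated record has 117/194 = 60% of countries without any point
  expect_gt(frac_zero, 0.5)
  expect_lt(frac_zero, 0.7)
  # per-country rows come in urban+rural pairs per drawn point count
  per_country <- dplyr::count(g$points, country_id)
  expect_true(all(per_country$n %% 2 == 0))
  expect_true(all(g$points$proportion > 0 & g$points$proportion < 1))
  # surveyed countries are almost exclusively low- and middle-income
  surveyed <- g$covariates[g$covariates$country_id %in%
                             g$points$country_id, ]
  expect_lte(sum(surveyed$income_group == "high"), 3)
  expect_gte(sum(surveyed$income_group == "high"), 1)
})

test_that("survey generator rejects degenerate configurations", {
  co <- default_coeffs <- survey_gen_config()$true_coefficients
  co$urban$year_slope <- Inf
  expect_error(survey_gen_config(true_coefficients = co), "finite")
  expect_error(survey_gen_config(sigma_country = -1))
  expect_error(survey_gen_config(data_pattern = c(`0` = -1, `1` = 2)),
               "non-negative")
})

test_that("observation generator obeys the planted prevalence ratio", {
  # ~50k events, no clustering noise: facility stratum at 2 x baseline
  cfg <- obs_gen_config(n_studies = 1, study_regions = "AFR",
                        n_households = 12500, events_per_household = 4,
                        true_pr = 2,
                        baseline_prev_by_region = c(AFR = 0.12),
                        p_facility = 0.5, sigma_household = 0,
                        sigma_study = 0, seed = 21)
  o <- generate_observation_study(cfg)
  r <- o$records
  expect_gt(nrow(r), 40000)
  prev <- tapply(r$hwws, r$facility_present, mean)
  se1 <- sqrt(0.24 * 0.76 / sum(r$facility_present == 1))
  se0 <- sqrt(0.12 * 0.88 / sum(r$facility_present == 0))
  expect_lt(abs(prev[["1"]] - 0.24), 3 * se1)
  expect_lt(abs(prev[["0"]] - 0.12), 3 * se0)
  # analytic mixture: 0.5 * 0.12 + 0.5 * 0.24
  expect_lt(abs(mean(r$hwws) - 0.18), 3 * sqrt(0.18 * 0.82 / nrow(r)))
})

test_that("null facility effect leaves no stratum difference", {
  cfg <- obs_gen_config(true_pr = 1, n_households = 800,
                        sigma_household = 0, sigma_study = 0, seed = 5)
  r <- generate_observation_study(cfg)$records
  prev <- tapply(r$hwws, r$facility_present, mean)
  pool <- mean(r$hwws)
  se <- sqrt(pool * (1 - pool) *
               sum(1 / table(r$facility_present)))
  expect_lt(abs(prev[["1"]] - prev[["0"]]), 3 * se)
})

test_that("observation generator validates inputs and truncation", {
  expect_error(obs_gen_config(true_pr = 0), "positive")
  expect_error(obs_gen_config(baseline_prev_by_region = c(AFR = 1.2),
                              study_regions = rep("AFR", 9)),
               "in \\(0, 1\\)")
  expect_error(obs_gen_config(true_pr = 3,
                              baseline_prev_by_region = c(AFR = 0.5),
                              study_regions = rep("AFR", 9),
                              truncate = FALSE),
               "truncation disabled")
  # random effects can push probabilities past 1 when truncation is off
  cfg <- obs_gen_config(true_pr = 1.9,
                        baseline_prev_by_region = c(AFR = 0.5),
                        study_regions = rep("AFR", 9),
                        sigma_study = 2, truncate = FALSE, seed = 2)
  expect_error(generate_observation_study(cfg), "exceeds 1")
})

test_that("meta generator honours tau and study sizes", {
  # tau = 0, huge studies: every proportion sits at the configured mean
  m0 <- generate_meta_studies(
    meta_gen_config(tau = 0, size_range = c(50000L, 60000L), seed = 4))
  expect_true(all(abs(m0$studies$n_hwws / m0$studies$n_events - 0.5)
                  < 0.01))
  res0 <- pool_random_effects(m0$studies)
  expect_lt(res0$I2, 40)

  m <- generate_meta_studies(meta_gen_config(seed = 4))
  expect_true(all(m$studies$n_events >= 1))
  expect_true(all(m$studies$n_hwws >= 0 &
                    m$studies$n_hwws <= m$studies$n_events))
})

test_that("generated moments converge to configured truths as 1/sqrt(n)", {
  # survey: empirical SD of noise-free-vs-noisy gap shrinks with more points
  base <- obs_gen_config(n_studies = 1, study_regions = "AFR",
                         true_pr = 2,
                         baseline_prev_by_region = c(AFR = 0.12),
                         p_facility = 0.5, sigma_household = 0,
                         sigma_study = 0, seed = 31)
  err_at <- function(nh) {
    cfg <- obs_gen_config(n_studies = 1, study_regions = "AFR",
                          n_households = nh, events_per_household = 2,
                          true_pr = 2,
                          baseline_prev_by_region = c(AFR = 0.12),
                          p_facility = 0.5, sigma_household = 0,
                          sigma_study = 0, seed = 31)
    r <- generate_observation_study(cfg)$records
    abs(mean(r$hwws) - 0.18)
  }
  errs <- c(small = err_at(250), large = err_at(16000))
  # 8x the events: error should drop clearly (allow generous slack)
  expect_lt(errs["large"], errs["small"])
})
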