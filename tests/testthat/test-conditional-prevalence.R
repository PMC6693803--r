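test_that("descriptive summary books every event and stratum", {
  empty <- generate_observation_study(obs_gen_config(seed = 1))$records[0, ]
  d0 <- describe_pooled_data(empty)
  expect_identical(sum(d0$n_events), 0L)

  o <- generate_observation_study(obs_gen_config(seed = 13))
  d <- describe_pooled_data(o$records)
  all_row <- dplyr::filter(d, subset == "all", facility == "all")
  expect_identical(all_row$n_events, nrow(o$records))
  expect_identical(all_row$n_hwws, sum(o$records$hwws))
  # crude overall prevalence is the event-weighted mean of the strata
  strata <- dplyr::filter(d, subset == "all", facility != "all")
  expect_equal(all_row$prevalence,
               weighted.mean(strata$prevalence, strata$n_events),
               tolerance = 1e-12)
  # adult subset is smaller
  adult_row <- dplyr::filter(d, subset == "adults", facility == "all")
  expect_lt(adult_row$n_events, all_row$n_events)
})

test_that("degenerate observation inputs are rejected", {
  o <- generate_observation_study(obs_gen_config(seed = 2))
  one_study <- dplyr::filter(o$records, study_id == "S01")
  expect_error(fit_conditional_model(one_study), "2 studies")
  no_facility <- dplyr::mutate(o$records, facility_present = 0)
  expect_error(fit_conditional_model(no_facility), "facility strata")
})

test_that("listwise deletion of unobservable facility status is audited", {
  o <- generate_observation_study(obs_gen_config(seed = 3))
  r <- o$records
  r$facility_present[c(5, 50, 500)] <- NA
  fit <- fit_conditional_model(r, nAGQ = 0)
  expect_identical(fit$n_deleted, 3L)
  expect_identical(fit$n_events, nrow(r) - 3L)
})

test_that("separated strata fall back to the robust fixed-effects fit", {
  o <- generate_observation_study(obs_gen_config(seed = 4))
  r <- dplyr::mutate(o$records,
                     hwws = ifelse(facility_present == 1, 0, hwws))
  expect_warning(fit <- fit_conditional_model(r), "falling back")
  expect_identical(fit$method, "robust-glm")
})

test_that("prevalence ratio is the exponentiated facility coefficient", {
  fit <- manual_conditional_fit(facility = log(2), se_facility = 0)
  pr <- prevalence_ratio(fit)
  expect_equal(pr$pr, 2, tolerance = 1e-12)
  expect_equal(pr$ci_low, 2, tolerance = 1e-12)
  expect_equal(pr$ci_high, 2, tolerance = 1e-12)
  fit0 <- manual_conditional_fit(facility = 0, se_facility = 0.1)
  expect_equal(prevalence_ratio(fit0)$pr, 1, tolerance = 1e-12)
})

test_that("regional predictions share one prevalence ratio (no interaction)", {
  o <- generate_observation_study(obs_gen_config(seed = 6))
  fit <- fit_conditional_model(o$records, nAGQ = 0)
  pr <- exp(fit$coefficients[["facility_present"]])
  for (rg in fit$regions) {
    with_f <- predict_regional_prevalence(fit, rg, 1)
    without <- predict_regional_prevalence(fit, rg, 0)
    expect_equal(with_f$prevalence / without$prevalence, pr,
                 tolerance = 1e-9)
    expect_true(all(c(with_f$ci_low, without$ci_low) >= 0))
    expect_true(all(c(with_f$ci_high, without$ci_high) <= 1))
  }
  expect_error(predict_regional_prevalence(fit, "EUR", 1),
               "pooled_average_prediction")
})

test_that("regional predictions recover the generating prevalences", {
  # large homogeneous world: adjusted predictions near the planted values
  cfg <- obs_gen_config(n_studies = 8,
                        study_regions = rep(c("AFR", "SEAR"), each = 4),
                        n_households = 400, sigma_household = 0,
                        sigma_study = 0, seed = 8)
  o <- generate_observation_study(cfg)
  fit <- fit_conditional_model(o$records, nAGQ = 0)
  afr0 <- predict_regional_prevalence(fit, "AFR", 0)
  afr1 <- predict_regional_prevalence(fit, "AFR", 1)
  expect_lt(abs(afr0$prevalence - 0.071), 0.02)
  expect_lt(abs(afr1$prevalence - 0.142), 0.04)
  sear0 <- predict_regional_prevalence(fit, "SEAR", 0)
  expect_lt(abs(sear0$prevalence - 0.163), 0.03)
})

test_that("pooled-average predictions cover unrepresented regions", {
  fit <- manual_conditional_fit(intercept = log(0.1), facility = log(2),
                                n_studies = 4)
  # identical country-level values: zero-width interval at the common value
  pooled <- pooled_average_prediction(fit, "EMR", 0)
  expect_equal(pooled$prevalence, 0.1, tolerance = 1e-12)
  expect_equal(pooled$ci_low, pooled$ci_high, tolerance = 1e-12)
  # EMR and EUR receive identical pooled rows by construction
  o <- generate_observation_study(obs_gen_config(seed = 10))
  mfit <- fit_conditional_model(o$records, nAGQ = 0)
  tab <- regional_prevalence_table(mfit)
  emr <- dplyr::filter(tab, who_region == "EMR")
  eur <- dplyr::filter(tab, who_region == "EUR")
  expect_equal(emr$prevalence, eur$prevalence, tolerance = 1e-12)
  expect_identical(unique(emr$provenance), "pooled-average")
  expect_true(all(tab$ci_low >= 0 & tab$ci_high <= 1))
  expect_true(all(tab$ci_low <= tab$prevalence &
                    tab$prevalence <= tab$ci_high))
})

test_that("robust SEs exceed naive SEs under intra-cluster correlation", {
  # Poisson model SEs on binary outcomes are inflated by the mean-variance
  # misspecification, so the clustering effect is isolated by comparing the
  # study-clustered sandwich with its working-independence counterpart
  # clustering at the household (facility is a household-level exposure, so
  # household ICC is what inflates the facility-coefficient variance; with
  # ~1800 household clusters the sandwich has negligible small-sample bias,
  # unlike the nine-study version whose downward bias is absorbed by the t
  # reference tested in the calibration study)
  cfg <- obs_gen_config(sigma_household = 0.8, sigma_study = 0.5,
                        seed = 14)
  o <- generate_observation_study(cfg)
  fit <- suppressWarnings(fit_conditional_model(o$records, nAGQ = 0))
  naive <- stats::glm(hwws ~ facility_present + who_region,
                      family = poisson, data = fit$data)
  hh_cl <- sandwich::vcovCL(naive, cluster = fit$data$household_key)
  indep <- sandwich::vcovHC(naive, type = "HC0")
  expect_gt(sqrt(hh_cl["facility_present", "facility_present"]),
            sqrt(indep["facility_present", "facility_present"]))
})
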