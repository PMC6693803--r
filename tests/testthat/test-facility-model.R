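test_that("noise-free data recovers the generating fixed effects", {
  g <- generate_survey_points(noise_free_config(seed = 2))
  fit <- fit_facility_mlm(g$points, g$covariates, "urban")
  co <- g$truth$coefficients$urban
  expect_equal(unname(fit$fixed_effects["year_c"]), co$year_slope,
               tolerance = 1e-6)
  # intercept re-centred to the generator's centring year
  b0 <- fit$fixed_effects["(Intercept)"] -
    fit$fixed_effects["year_c"] * (g$truth$year_center - fit$year_center)
  expect_equal(unname(b0), co$intercept, tolerance = 1e-6)
  for (rg in c("AMR", "EUR", "WPR")) {
    expect_equal(unname(fit$fixed_effects[paste0("who_region", rg)]),
                 co$region[[rg]], tolerance = 1e-5)
  }
  # fitted values reproduce the data exactly
  pred <- predict_presence(fit, unique(g$points$country_id), 2015)
  joined <- dplyr::inner_join(
    pred, dplyr::inner_join(g$covariates, g$truth$random_intercepts,
                            by = "country_id"),
    by = "country_id")
  truthv <- purrr::pmap_dbl(
    joined[c("who_region", "income_group", "urban")],
    \(who_region, income_group, urban)
      true_presence(g$truth, "urban", who_region, income_group, 2015,
                    urban))
  expect_equal(joined$estimate, truthv, tolerance = 1e-6)
})

test_that("single-country data fails with an informative message", {
  g <- generate_survey_points(small_world_config(seed = 4))
  one <- dplyr::filter(g$points,
                       country_id == dplyr::first(g$points$country_id))
  expect_error(fit_facility_mlm(one, g$covariates, "urban"),
               "at least 2 countries")
})

test_that("null coefficients predict one half everywhere", {
  co <- list(intercept = 0, year_slope = 0,
             region = c(AMR = 0, EMR = 0, EUR = 0, SEAR = 0, WPR = 0),
             income = c(`lower-middle` = 0, `upper-middle` = 0, high = 0))
  cfg <- small_world_config(seed = 6, sigma_country = 0, sigma_resid = 0,
                            true_coefficients = list(urban = co,
                                                     rural = co))
  g <- generate_survey_points(cfg)
  fit <- fit_facility_mlm(g$points, g$covariates, "urban")
  pred <- predict_presence(fit, g$covariates$country_id, 2015)
  expect_equal(pred$estimate, rep(0.5, nrow(pred)), tolerance = 1e-6)
})

test_that("extrapolated countries get the fixed part and a basis flag", {
  g <- generate_survey_points(small_world_config(seed = 9))
  fit <- fit_facility_mlm(g$points, g$covariates, "urban")
  nodata <- setdiff(g$covariates$country_id, g$points$country_id)
  expect_gt(length(nodata), 0)
  p <- predict_presence(fit, nodata[1], 2012)
  expect_identical(p$basis, "extrapolated")
  # recompute the fixed part by hand from the fitted coefficients
  row <- g$covariates[g$covariates$country_id == nodata[1], ]
  b <- fit$fixed_effects
  eta <- b[["(Intercept)"]] + b[["year_c"]] * (2012 - fit$year_center)
  rg <- paste0("who_region", row$who_region)
  ic <- paste0("income_group", row$income_group)
  if (rg %in% names(b)) eta <- eta + b[[rg]]
  if (ic %in% names(b)) eta <- eta + b[[ic]]
  expect_equal(p$estimate, plogis(eta), tolerance = 1e-12)
  expect_error(predict_presence(fit, "NOPE", 2015), "Unknown country")
})

test_that("Monte-Carlo intervals bracket the estimate and live in [0,1]", {
  g <- generate_survey_points(small_world_config(seed = 12))
  fit <- fit_facility_mlm(g$points, g$covariates, "urban")
  own <- intersect(g$covariates$country_id, g$points$country_id)
  for (cid in own[1:5]) {
    ci <- monte_carlo_ci(fit, cid, 2015, n_draws = 500, seed = 1)
    expect_gte(ci$estimate, ci$ci_low)
    expect_lte(ci$estimate, ci$ci_high)
    expect_gte(ci$ci_low, 0)
    expect_lte(ci$ci_high, 1)
  }
  # deterministic under seed
  c1 <- monte_carlo_ci(fit, own[1], 2015, n_draws = 500, seed = 3)
  c2 <- monte_carlo_ci(fit, own[1], 2015, n_draws = 500, seed = 3)
  expect_identical(c1, c2)
  # zero variance collapses the interval onto the point estimate
  ci0 <- monte_carlo_ci(zero_variance_fit(fit), own[1], 2015,
                        n_draws = 200, seed = 1)
  expect_equal(ci0$ci_low, ci0$estimate, tolerance = 1e-12)
  expect_equal(ci0$ci_high, ci0$estimate, tolerance = 1e-12)
  # no-data countries are directed to the prediction-interval route
  nodata <- setdiff(g$covariates$country_id, own)
  expect_error(monte_carlo_ci(fit, nodata[1], 2015),
               "prediction_interval_no_data")
})

test_that("regional prediction intervals behave like textbook PIs", {
  cov <- tibble::tibble(country_id = sprintf("C%02d", 1:6),
                        who_region = c(rep("AFR", 4), "AMR", "AMR"),
                        income_group = "low",
                        pop_urban = 1e6, pop_rural = 1e6)
  # AFR points exactly on a flat logit line: zero residual, zero width
  pts <- tibble::tibble(
    country_id = rep(sprintf("C%02d", 1:4), each = 2),
    year = rep(c(2005, 2010, 2006, 2012), each = 2),
    stratum = rep(c("urban", "rural"), 4),
    proportion = plogis(0.3),
    source = "fixture")
  expect_equal(prediction_interval_no_data(pts, cov, "AFR", "urban", 2015),
               0, tolerance = 1e-8)
  expect_error(prediction_interval_no_data(pts, cov, "AMR", "urban", 2015),
               "fewer than 2")
  # noisy flat series: widths grow away from the mean data year
  set.seed(42)
  pts2 <- tibble::tibble(
    country_id = rep(sprintf("C%02d", 1:4), 3),
    year = rep(c(2004, 2008, 2012), each = 4),
    stratum = "urban",
    proportion = plogis(rnorm(12, 0, 0.4)),
    source = "fixture")
  w <- vapply(c(2008, 2012, 2016, 2020), function(yr)
    prediction_interval_no_data(pts2, cov, "AFR", "urban", yr), 0)
  expect_true(all(diff(w) > 0))
})

test_that("stratum combination follows the delta method", {
  cov <- tibble::tibble(country_id = c("A", "B", "C"),
                        who_region = "AFR", income_group = "low",
                        pop_urban = c(3e6, 5e6, 2e6),
                        pop_rural = c(1e6, 0, 2e6))
  mk <- function(est, se) {
    z <- qnorm(0.975)
    tibble::tibble(country_id = c("A", "B", "C"), estimate = est,
                   ci_low = est - z * se, ci_high = est + z * se,
                   basis = "own-data")
  }
  # equal stratum values: combined equals the common value for any weights
  comb <- combine_strata(mk(c(0.4, 0.7, 0.2), c(0.02, 0.03, 0.01)),
                         mk(c(0.4, 0.7, 0.2), c(0.02, 0.03, 0.01)), cov)
  expect_equal(comb$estimate, c(0.4, 0.7, 0.2), tolerance = 1e-12)
  # zero rural population: country B inherits the urban estimate and CI
  u <- mk(c(0.4, 0.7, 0.2), c(0.02, 0.03, 0.01))
  r <- mk(c(0.1, 0.2, 0.6), c(0.05, 0.05, 0.01))
  comb2 <- combine_strata(u, r, cov)
  expect_equal(comb2$estimate[2], 0.7, tolerance = 1e-12)
  expect_equal(comb2$ci_low[2], u$ci_low[2], tolerance = 1e-9)
  # country C: equal weights, SE 0.01 in both strata -> combined s/sqrt(2)
  expect_equal(comb2$se[3], 0.01 / sqrt(2), tolerance = 1e-9)
  cov0 <- dplyr::mutate(cov, pop_urban = 0, pop_rural = 0)
  expect_error(combine_strata(u, r, cov0), "population")
})

test_that("aggregation is population-weighted with quadrature SEs", {
  cov <- tibble::tibble(country_id = sprintf("C%d", 1:10),
                        who_region = "SEAR", income_group = "lower-middle",
                        pop_urban = runif(10, 1e5, 1e7),
                        pop_rural = runif(10, 1e5, 1e7))
  se <- runif(10, 0.01, 0.08)
  est <- tibble::tibble(country_id = cov$country_id,
                        estimate = runif(10, 0.2, 0.8),
                        ci_low = NA, ci_high = NA)
  est$ci_low <- est$estimate - qnorm(0.975) * se
  est$ci_high <- est$estimate + qnorm(0.975) * se
  agg <- aggregate_estimates(est, cov, "region_income")
  w <- (cov$pop_urban + cov$pop_rural) /
    sum(cov$pop_urban + cov$pop_rural)
  expect_equal(agg$estimate, sum(w * est$estimate), tolerance = 1e-12)
  # brute-force delta SE
  se_expected <- sqrt(sum(w^2 * se^2))
  se_got <- (agg$ci_high - agg$ci_low) / (2 * qnorm(0.975))
  expect_equal(se_got, se_expected, tolerance = 1e-9)
  # degenerate weights: single positive population picks that country
  cov1 <- dplyr::mutate(cov, pop_urban = c(1e6, rep(0, 9)),
                        pop_rural = 0)
  agg1 <- aggregate_estimates(est, cov1, "world")
  expect_equal(agg1$estimate, est$estimate[1], tolerance = 1e-12)
  expect_error(aggregate_estimates(est[0, ], cov, "world"), "Empty group")
})

test_that("stratum-then-country aggregation equals direct cell weighting", {
  g <- generate_survey_points(small_world_config(seed = 15))
  cov <- g$covariates
  mk <- function(n, seed) {
    set.seed(seed)
    tibble::tibble(country_id = cov$country_id,
                   estimate = runif(n, 0.1, 0.9),
                   se = runif(n, 0.01, 0.05)) |>
      dplyr::mutate(ci_low = estimate - qnorm(0.975) * se,
                    ci_high = estimate + qnorm(0.975) * se,
                    basis = "own-data")
  }
  u <- mk(nrow(cov), 1)
  r <- mk(nrow(cov), 2)
  combined <- combine_strata(u, r, cov)
  world <- aggregate_estimates(combined, cov, "world")
  pop <- cov$pop_urban + cov$pop_rural
  direct <- (sum(cov$pop_urban * u$estimate) +
               sum(cov$pop_rural * r$estimate)) / sum(pop)
  expect_equal(world$estimate, direct, tolerance = 1e-12)
})

test_that("leave-one-out cross-validation matches a naive refit oracle", {
  cfg <- small_world_config(seed = 18, sigma_resid = 0.25)
  g <- generate_survey_points(cfg)
  has_2015 <- any(g$points$year == 2015 & g$points$stratum == "urban")
  expect_true(has_2015)
  res <- loo_cv_rmse(g$points, g$covariates, 2015, "urban")
  expect_gte(res$rmse, 0)
  # order invariance
  shuffled <- g$points[sample(nrow(g$points)), ]
  expect_equal(loo_cv_rmse(shuffled, g$covariates, 2015, "urban")$rmse,
               res$rmse, tolerance = 1e-6)
  # independent oracle: explicit loop over lme4 refits
  oracle_rmse <- loo_oracle_rmse(g$points, g$covariates, 2015, "urban")
  expect_lt(abs(res$rmse - oracle_rmse), 0.25 * oracle_rmse + 1e-8)
})

test_that("noise-free leave-one-out error is numerically zero", {
  g <- generate_survey_points(noise_free_config(seed = 20))
  if (!any(g$points$year == 2015 & g$points$stratum == "urban")) {
    g <- generate_survey_points(noise_free_config(seed = 21))
  }
  res <- loo_cv_rmse(g$points, g$covariates, 2015, "urban")
  expect_lt(res$rmse, 1e-3)
})

test_that("the recency filter keeps qualifying rows and reports removals", {
  pts <- tibble::tibble(country_id = "A", year = c(2001, 2008, 2009, 2015),
                        stratum = "urban", proportion = 0.5, source = "x")
  all_kept <- filter_since(pts, 1990)
  expect_identical(nrow(all_kept), 4L)
  expect_identical(attr(all_kept, "n_removed"), 0L)
  some <- filter_since(pts, 2009)
  expect_identical(nrow(some), 2L)
  expect_identical(attr(some, "n_removed"), 2L)
  expect_true(all(some$year >= 2009))
  expect_warning(filter_since(pts, 2030), "No survey points")
})
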