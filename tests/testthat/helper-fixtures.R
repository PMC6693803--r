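# Small worlds for fast model fits ------------------------------------------

# ~48 countries, every region x income cell occupied, denser data than the
# default world so every fit in unit tests is well-conditioned
small_world_config <- function(seed = 1, sigma_country = 0.5,
                               sigma_resid = 0.3, ...) {
  tab <- tidyr::crossing(who_region = c("AFR", "AMR", "EMR", "EUR",
                                        "SEAR", "WPR"),
                         income_group = c("low", "lower-middle",
                                          "upper-middle", "high")) |>
    dplyr::mutate(n = 2L)
  survey_gen_config(n_countries_per_region_income = tab,
                    data_pattern = c(`0` = 1, `2` = 2, `3` = 1),
                    sigma_country = sigma_country,
                    sigma_resid = sigma_resid,
                    seed = seed, ...)
}

# noise-free world: every generated proportion is an exact inverse-logit of
# the fixed part
noise_free_config <- function(seed = 1, ...) {
  small_world_config(seed = seed, sigma_country = 0, sigma_resid = 0, ...)
}

# a facility_fit whose uncertainty is artificially zeroed, for degenerate
# CI checks
zero_variance_fit <- function(fit) {
  fit$vcov_fixed[] <- 0
  fit$random_intercepts$cond_sd <- 0
  fit
}

# hand-built conditional fit: single region, no random effects, known
# coefficients, for closed-form prediction checks
manual_conditional_fit <- function(intercept = log(0.071),
                                   facility = log(2),
                                   se_facility = 0,
                                   n_studies = 3) {
  beta <- c("(Intercept)" = intercept, facility_present = facility)
  V <- matrix(0, 2, 2, dimnames = list(names(beta), names(beta)))
  V["facility_present", "facility_present"] <- se_facility^2
  dat <- tibble::tibble(
    study_id = sprintf("S%02d", seq_len(n_studies)),
    country_id = sprintf("C%02d", seq_len(n_studies)),
    who_region = "AFR")
  structure(
    list(coefficients = beta, robust_vcov = V, naive_vcov = V,
         varcomp = c(household = 0, study = 0), df_t = n_studies - 1,
         method = "robust-glm", model = NULL,
         event_class = "faecal_contact", adults_only = FALSE,
         regions = "AFR", n_events = 0L, n_households = 0L,
         n_studies = n_studies, n_deleted = 0L, data = dat),
    class = "conditional_fit")
}

# meta_result with prescribed pooled value and SE, for combiner tests
manual_meta_result <- function(pooled = 0.506, se = 0.0406) {
  structure(
    list(pooled = pooled,
         ci_low = pooled - qnorm(0.975) * se,
         ci_high = pooled + qnorm(0.975) * se,
         se = se, tau2 = 0, Q = 0, df = 1, I2 = 0, scale = "proportion",
         studies = tibble::tibble(study_id = c("A", "B"),
                                  n_events = c(100L, 100L),
                                  n_hwws = c(51L, 50L),
                                  p = c(0.51, 0.50),
                                  yi = c(0.51, 0.50),
                                  vi = c(0.0025, 0.0025),
                                  weight = c(0.5, 0.5))),
    class = "meta_result")
}

# independent leave-one-out oracle: an explicit loop of lme4 refits with
# its own clamp/centring code, used to cross-check loo_cv_rmse()
loo_oracle_rmse <- function(points, covariates, target_year = 2015,
                            stratum = "urban") {
  test_ctry <- points |>
    dplyr::filter(.data$year == target_year, .data$stratum == !!stratum) |>
    dplyr::distinct(.data$country_id, .keep_all = TRUE)
  errs <- vapply(seq_len(nrow(test_ctry)), function(i) {
    cid <- test_ctry$country_id[i]
    d <- points |>
      dplyr::filter(.data$stratum == !!stratum, .data$country_id != cid) |>
      dplyr::inner_join(covariates, by = "country_id")
    d$y <- qlogis(pmin(pmax(d$proportion, 0.005), 0.995))
    d$yc <- d$year - median(d$year)
    m <- lme4::lmer(y ~ yc + who_region + income_group + (1 | country_id),
                    data = d, REML = FALSE)
    nd <- covariates[covariates$country_id == cid, ]
    X <- model.matrix(
      ~ yc + who_region + income_group,
      data = dplyr::mutate(
        nd, yc = target_year - median(d$year),
        who_region = factor(who_region, levels(factor(d$who_region))),
        income_group = factor(income_group,
                              levels(factor(d$income_group)))))
    plogis(drop(X %*% lme4::fixef(m))) - test_ctry$proportion[i]
  }, 0)
  100 * sqrt(mean(errs^2))
}

# closed-form fixed-part proportion of the survey generator
true_presence <- function(truth, stratum, who_region, income_group, year,
                          country_intercept = 0) {
  co <- truth$coefficients[[stratum]]
  eta <- co$intercept + co$year_slope * (year - truth$year_center) +
    c(AFR = 0, co$region)[[who_region]] +
    c(low = 0, co$income)[[income_group]] + country_intercept
  plogis(eta)
}
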