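#' Fit the logit-scale multilevel model of facility presence
#'
#' Fits a two-level linear multilevel model to logit-transformed survey
#' proportions of households with a designated handwashing facility: survey
#' points cluster within countries via a country random intercept, and the
#' fixed part is a linear year trend (centred by the median survey year),
#' WHO-region contrasts and 2015 income-group contrasts. Urban and rural
#' series are fitted separately.
#'
#' Proportions are clamped to `[clamp, 1 - clamp]` before the logit since
#' boundary proportions occur at small survey samples. Estimation is by
#' maximum likelihood by default so fixed effects are comparable across
#' leave-one-out refits; set `reml = TRUE` for restricted ML.
#'
#' @param points tibble of survey points: `country_id`, `year`, `stratum`,
#'   `proportion` (and optionally `source`).
#' @param covariates tibble: `country_id`, `who_region`, `income_group`,
#'   `pop_urban`, `pop_rural`.
#' @param stratum `"urban"` or `"rural"`.
#' @param clamp boundary clamp for the logit transform.
#' @param reml use REML instead of ML.
#' @return a `facility_fit` object: fixed effects and their covariance,
#'   per-country random intercepts (BLUPs with conditional SDs), variance
#'   components, the centring year and the covariate table.
#' @export
fit_facility_mlm <- function(points, covariates, stratum,
                             clamp = 0.005, reml = FALSE) {
  stopifnot(is.data.frame(points), is.data.frame(covariates))
  stratum <- match.arg(stratum, c("urban", "rural"))
  dat <- points |>
    dplyr::filter(.data$stratum == !!stratum) |>
    dplyr::inner_join(covariates, by = "country_id")
  if (dplyr::n_distinct(dat$country_id) < 2) {
    abort(paste0("Need survey points from at least 2 countries to fit the ",
                 "multilevel model (got ",
                 dplyr::n_distinct(dat$country_id), ")."))
  }
  y <- safe_logit(dat$proportion, clamp)
  n_clamped <- attr(y, "n_clamped")
  year_center <- median(dat$year)
  dat <- dat |>
    dplyr::mutate(
      .y = as.numeric(y),
      year_c = .data$year - year_center,
      who_region = factor(.data$who_region,
                          levels = intersect(WHO_REGIONS, .data$who_region)),
      income_group = factor(.data$income_group,
                            levels = intersect(INCOME_GROUPS,
                                               .data$income_group))
    )

  terms <- c("year_c",
             if (nlevels(dat$who_region) > 1) "who_region",
             if (nlevels(dat$income_group) > 1) "income_group")
  fixed <- paste(".y ~", paste(terms, collapse = " + "))
  mm <- model.matrix(as.formula(paste("~", paste(terms, collapse = " + "))),
                     dat)
  qrk <- qr(mm)
  if (qrk$rank < ncol(mm)) {
    bad <- colnames(mm)[qrk$pivot[(qrk$rank + 1):ncol(mm)]]
    abort(paste0("Singular fixed-effect design: no data separates ",
                 paste(bad, collapse = ", "),
                 " from the remaining region/income cells."))
  }
  model <- lme4::lmer(as.formula(paste(fixed, "+ (1 | country_id)")),
                      data = dat, REML = reml)

  re <- lme4::ranef(model, condVar = TRUE)$country_id
  cond_sd <- sqrt(as.numeric(attr(re, "postVar")))
  vc <- as.data.frame(lme4::VarCorr(model))
  vcov_fixed <- suppressWarnings(
    as.matrix(vcov(model, correlation = FALSE)))
  if (anyNA(vcov_fixed)) {
    # a noise-free fit has an exactly singular covariance
    if (stats::sigma(model) < 1e-6) {
      vcov_fixed[] <- 0
    } else {
      abort("Fixed-effect covariance could not be computed.")
    }
  }
  structure(
    list(stratum = stratum,
         model = model,
         fixed_effects = lme4::fixef(model),
         vcov_fixed = vcov_fixed,
         random_intercepts = tibble::tibble(
           country_id = rownames(re),
           intercept = re[["(Intercept)"]],
           cond_sd = cond_sd),
         sigma2_country = vc$vcov[vc$grp == "country_id"],
         sigma2_resid = vc$vcov[vc$grp == "Residual"],
         year_center = year_center,
         covariates = covariates,
         xlevels = list(who_region = levels(dat$who_region),
                        income_group = levels(dat$income_group)),
         clamp = clamp,
         n_points = nrow(dat),
         n_countries = dplyr::n_distinct(dat$country_id),
         n_clamped = n_clamped),
    class = "facility_fit")
}

#' @export
print.facility_fit <- function(x, ...) {
  cat("Facility-presence multilevel model (", x$stratum, " stratum)\n",
      sep = "")
  cat("  survey points:", x$n_points, "in", x$n_countries, "countries\n")
  cat("  variance components (logit scale): country",
      signif(x$sigma2_country, 4), "| residual",
      signif(x$sigma2_resid, 4), "\n")
  cat("  year centred at", x$year_center, "\n")
  invisible(x)
}

# fixed-part design row aligned with the fitted coefficient names;
# unseen region/income levels fall back to the reference level (logged)
facility_design_row <- function(fit, who_region, income_group, year) {
  nm <- names(fit$fixed_effects)
  x <- setNames(numeric(length(nm)), nm)
  x["(Intercept)"] <- 1
  if ("year_c" %in% nm) x["year_c"] <- year - fit$year_center
  reg_col <- paste0("who_region", who_region)
  inc_col <- paste0("income_group", income_group)
  fallback <- character(0)
  if (reg_col %in% nm) {
    x[reg_col] <- 1
  } else if (!who_region %in% fit$xlevels$who_region) {
    fallback <- c(fallback, who_region)  # unseen region -> reference level
  }
  if (inc_col %in% nm) {
    x[inc_col] <- 1
  } else if (!income_group %in% fit$xlevels$income_group) {
    fallback <- c(fallback, income_group)  # unseen income -> reference level
  }
  attr(x, "fallback") <- fallback
  x
}

#' Predict facility presence for a country and year
#'
#' For countries with their own survey data the prediction is the
#' inverse-logit of the fixed-part predictor plus the country's random
#' intercept (BLUP). Countries without data receive the fixed part alone —
#' the mean value for their year, region and income group — and are flagged
#' `extrapolated`.
#'
#' @param fit a [fit_facility_mlm()] result.
#' @param country_id character vector of country codes (must appear in the
#'   covariate table used for fitting).
#' @param year prediction year (scalar or vector matching `country_id`).
#' @return tibble: `country_id`, `stratum`, `year`, `estimate`, `basis`.
#' @export
predict_presence <- function(fit, country_id, year) {
  stopifnot(inherits(fit, "facility_fit"))
  cov <- fit$covariates
  unknown <- setdiff(country_id, cov$country_id)
  if (length(unknown)) {
    abort(paste0("Unknown country id(s): ",
                 paste(unknown, collapse = ", ")))
  }
  year <- rep_len(year, length(country_id))
  re <- fit$random_intercepts
  purrr::map2(country_id, year, function(cid, yr) {
    row <- cov[cov$country_id == cid, ]
    x <- facility_design_row(fit, row$who_region, row$income_group, yr)
    eta <- sum(x * fit$fixed_effects)
    has_data <- cid %in% re$country_id
    if (has_data) eta <- eta + re$intercept[re$country_id == cid]
    tibble::tibble(country_id = cid, stratum = fit$stratum, year = yr,
                   estimate = plogis(eta),
                   basis = if (has_data) "own-data" else "extrapolated")
  }) |> dplyr::bind_rows()
}

#' Monte-Carlo confidence interval for a country with survey data
#'
#' Draws `n_draws` fixed-effect vectors from a multivariate normal with the
#' fitted covariance and, jointly, the target country's random intercept
#' from its conditional (posterior) normal, then takes the empirical 2.5 and
#' 97.5 percentiles of the inverse-logit predictions.
#'
#' @param fit a [fit_facility_mlm()] result.
#' @param country_id single country code with survey data.
#' @param year prediction year.
#' @param n_draws number of Monte-Carlo draws (default 10 000).
#' @param seed integer seed for reproducibility.
#' @return tibble: `country_id`, `stratum`, `year`, `estimate`, `ci_low`,
#'   `ci_high`.
#' @export
monte_carlo_ci <- function(fit, country_id, year, n_draws = 10000,
                           seed = NULL) {
  stopifnot(inherits(fit, "facility_fit"), length(country_id) == 1)
  re <- fit$random_intercepts
  if (!country_id %in% re$country_id) {
    abort(paste0("Country ", country_id, " has no survey data; use ",
                 "prediction_interval_no_data() for extrapolated countries."))
  }
  row <- fit$covariates[fit$covariates$country_id == country_id, ]
  x <- facility_design_row(fit, row$who_region, row$income_group, year)
  i <- match(country_id, re$country_id)
  with_local_seed(seed, {
    beta <- MASS::mvrnorm(n_draws, mu = fit$fixed_effects,
                          Sigma = fit$vcov_fixed)
    b <- rnorm(n_draws, re$intercept[i], re$cond_sd[i])
    p <- plogis(drop(beta %*% x) + b)
    qs <- quantile(p, c(0.025, 0.975), names = FALSE)
    tibble::tibble(country_id = country_id, stratum = fit$stratum,
                   year = year,
                   estimate = plogis(sum(x * fit$fixed_effects) +
                                       re$intercept[i]),
                   ci_low = qs[1], ci_high = qs[2])
  })
}

#' Prediction-interval width for countries without survey data
#'
#' Countries without survey points have no random intercept to vary, so
#' their uncertainty is approximated by the 95% prediction interval of an
#' ordinary fixed-effects linear regression of the region's logit
#' proportions on year. The interval limits are back-transformed to the
#' proportion scale and their width `PI` returned; the caller forms
#' confidence limits as `estimate +/- PI/2`, truncated to `[0, 1]`.
#'
#' @param points survey-point tibble (all strata).
#' @param covariates covariate tibble.
#' @param region WHO region code.
#' @param stratum `"urban"` or `"rural"`.
#' @param year target year.
#' @param clamp boundary clamp for the logit transform.
#' @return single numeric: the proportion-scale width of the 95% prediction
#'   interval at `year`.
#' @export
prediction_interval_no_data <- function(points, covariates, region, stratum,
                                        year, clamp = 0.005) {
  stratum <- match.arg(stratum, c("urban", "rural"))
  dat <- points |>
    dplyr::filter(.data$stratum == !!stratum) |>
    dplyr::inner_join(covariates, by = "country_id") |>
    dplyr::filter(.data$who_region == region)
  if (nrow(dat) < 2) {
    abort(paste0("Region ", region, " has fewer than 2 ", stratum,
                 " survey points; no prediction interval available."))
  }
  dat$.y <- as.numeric(safe_logit(dat$proportion, clamp))
  m <- lm(.y ~ year, data = dat)
  pr <- suppressWarnings(
    predict(m, newdata = data.frame(year = year), interval = "prediction",
            level = 0.95))
  width <- plogis(pr[1, "upr"]) - plogis(pr[1, "lwr"])
  if (!is.finite(width)) {
    abort(paste0("Prediction interval for region ", region,
                 " is undefined (zero residual degrees of freedom)."))
  }
  width
}

#' Combine urban and rural estimates into a country estimate
#'
#' The country estimate is the population-weighted mean of the urban and
#' rural modelled values. Its standard error is a delta-method combination
#' treating the strata as independent, `SE^2 = w_u^2 SE_u^2 + w_r^2 SE_r^2`,
#' with stratum SEs recovered from the CI half-widths on the proportion
#' scale; the normal-approximation CI is truncated to `[0, 1]`.
#'
#' @param urban_est,rural_est tibbles with `country_id`, `estimate`,
#'   `ci_low`, `ci_high` and optionally `basis`, one row per country.
#' @param covariates covariate tibble with `pop_urban`, `pop_rural`.
#' @return tibble with `stratum = "combined"`, one row per country.
#' @export
combine_strata <- function(urban_est, rural_est, covariates) {
  dat <- dplyr::inner_join(urban_est, rural_est, by = "country_id",
                           suffix = c("_u", "_r")) |>
    dplyr::inner_join(covariates, by = "country_id")
  if (any(dat$pop_urban + dat$pop_rural <= 0)) {
    abort("Zero total population for at least one country.")
  }
  dat |>
    dplyr::mutate(
      w_u = .data$pop_urban / (.data$pop_urban + .data$pop_rural),
      w_r = 1 - .data$w_u,
      estimate = .data$w_u * .data$estimate_u + .data$w_r * .data$estimate_r,
      se = sqrt(.data$w_u^2 * se_from_ci(.data$ci_low_u, .data$ci_high_u)^2 +
                  .data$w_r^2 * se_from_ci(.data$ci_low_r,
                                           .data$ci_high_r)^2),
      ci_low = truncate01(.data$estimate - qnorm(0.975) * .data$se),
      ci_high = truncate01(.data$estimate + qnorm(0.975) * .data$se),
      stratum = "combined",
      basis = if (all(c("basis_u", "basis_r") %in% names(dat))) {
        ifelse(.data$basis_u == "own-data" & .data$basis_r == "own-data",
               "own-data", "extrapolated")
      } else {
        NA_character_
      }
    ) |>
    dplyr::select("country_id", "stratum", dplyr::any_of("year_u"),
                  "estimate", "se", "ci_low", "ci_high", "basis") |>
    dplyr::rename(dplyr::any_of(c(year = "year_u")))
}

#' Population-weighted aggregation of country estimates
#'
#' Aggregates country-level facility estimates to groups (WHO region within
#' income class, income class, or the world) as population-weighted means,
#' with delta-method SEs `sqrt(sum(w_i^2 SE_i^2))` treating countries as
#' independent.
#'
#' @param country_estimates tibble with `country_id`, `estimate`, `ci_low`,
#'   `ci_high` (one row per country; typically [combine_strata()] output).
#' @param covariates covariate tibble (for populations, region and income).
#' @param grouping one of `"region_income"`, `"income"`, `"world"`.
#' @return tibble: `group`, `estimate`, `ci_low`, `ci_high`, `n_countries`.
#' @export
aggregate_estimates <- function(country_estimates, covariates,
                                grouping = c("region_income", "income",
                                             "world")) {
  grouping <- match.arg(grouping)
  dat <- country_estimates |>
    dplyr::inner_join(covariates, by = "country_id") |>
    dplyr::mutate(
      population = .data$pop_urban + .data$pop_rural,
      income_class = ifelse(.data$income_group == "high", "HIC", "LMI"),
      group = switch(grouping,
                     region_income = paste(.data$who_region,
                                           .data$income_class),
                     income = .data$income_class,
                     world = "World"),
      se = se_from_ci(.data$ci_low, .data$ci_high)
    )
  if (nrow(dat) == 0) abort("Empty group: no countries to aggregate.")
  dat |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n_countries = dplyr::n(),
      w_se2 = sum((.data$population / sum(.data$population))^2 * .data$se^2),
      estimate = weighted.mean(.data$estimate, .data$population),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      ci_low = truncate01(.data$estimate - qnorm(0.975) * sqrt(.data$w_se2)),
      ci_high = truncate01(.data$estimate + qnorm(0.975) * sqrt(.data$w_se2))
    ) |>
    dplyr::select("group", "estimate", "ci_low", "ci_high", "n_countries")
}

#' Leave-one-out cross-validation RMSE of the facility model
#'
#' For each country with a survey point in `target_year`, the model is refit
#' with all of that country's points removed, the country's `target_year`
#' value predicted (necessarily from the fixed part alone), and the
#' root-mean-squared error across rounds reported in percentage points.
#'
#' @param points survey-point tibble.
#' @param covariates covariate tibble.
#' @param target_year year whose survey values form the test sets.
#' @param stratum `"urban"` or `"rural"`.
#' @param ... passed to [fit_facility_mlm()].
#' @return list: `rmse` (percentage points), `n_rounds`, and `rounds`
#'   (tibble of per-country predictions vs observed values).
#' @export
loo_cv_rmse <- function(points, covariates, target_year = 2015,
                        stratum = "urban", ...) {
  stratum <- match.arg(stratum, c("urban", "rural"))
  test <- points |>
    dplyr::filter(.data$stratum == !!stratum, .data$year == target_year) |>
    dplyr::group_by(.data$country_id) |>
    dplyr::summarise(observed = mean(.data$proportion), .groups = "drop")
  if (nrow(test) < 1) {
    abort(paste0("No country has a ", stratum, " survey point in ",
                 target_year, "."))
  }
  rounds <- purrr::map(test$country_id, function(cid) {
    fold <- dplyr::filter(points, .data$country_id != cid)
    fit <- fit_facility_mlm(fold, covariates, stratum, ...)
    pred <- predict_presence(fit, cid, target_year)
    tibble::tibble(country_id = cid, predicted = pred$estimate)
  }) |>
    dplyr::bind_rows() |>
    dplyr::inner_join(test, by = "country_id")
  list(rmse = 100 * sqrt(mean((rounds$predicted - rounds$observed)^2)),
       n_rounds = nrow(rounds),
       rounds = rounds)
}

#' Restrict survey points to recent years
#'
#' Sensitivity filter keeping only survey points collected in or after
#' `min_year` (by default 2009, when survey instruments were harmonized).
#'
#' @param points survey-point tibble.
#' @param min_year first year to keep.
#' @return the qualifying subset, with attribute `n_removed`; warns if
#'   nothing remains.
#' @export
filter_since <- function(points, min_year = 2009) {
  out <- dplyr::filter(points, .data$year >= min_year)
  n_removed <- nrow(points) - nrow(out)
  if (nrow(out) == 0) {
    warn(paste0("No survey points remain at or after ", min_year, "."))
  }
  attr(out, "n_removed") <- n_removed
  out
}

#' Estimate facility presence for every country
#'
#' Objective-1 driver: fits the urban and rural multilevel models, predicts
#' every country in the covariate table at `target_year`, attaches
#' Monte-Carlo CIs for countries with data and prediction-interval CIs for
#' extrapolated countries, and combines strata into country estimates.
#'
#' @param points survey-point tibble.
#' @param covariates covariate tibble.
#' @param target_year prediction year (default 2015).
#' @param n_draws Monte-Carlo draws per country (default 10 000).
#' @param seed integer seed for the Monte-Carlo draws.
#' @param ... passed to [fit_facility_mlm()].
#' @return list: `by_stratum` (urban and rural estimate tibbles),
#'   `by_country` (combined estimates), `fits` (the two model objects).
#' @export
estimate_facilities <- function(points, covariates, target_year = 2015,
                                n_draws = 10000, seed = NULL, ...) {
  fits <- purrr::map(c(urban = "urban", rural = "rural"),
                     \(s) fit_facility_mlm(points, covariates, s, ...))
  by_stratum <- purrr::imap(fits, function(fit, str) {
    pred <- predict_presence(fit, covariates$country_id, target_year)
    # PI width per region, computed once and reused for all no-data countries
    regions <- unique(covariates$who_region[
      covariates$country_id %in%
        pred$country_id[pred$basis == "extrapolated"]])
    pi_w <- purrr::map_dbl(setNames(regions, regions), function(rg) {
      tryCatch(
        prediction_interval_no_data(points, covariates, rg, str,
                                    target_year),
        error = function(e) NA_real_)
    })
    # regions with too little data inherit the widest available interval
    if (anyNA(pi_w)) pi_w[is.na(pi_w)] <- max(pi_w, na.rm = TRUE)
    purrr::pmap(pred, function(country_id, stratum, year, estimate, basis) {
      if (basis == "own-data") {
        ci <- monte_carlo_ci(fit, country_id, year, n_draws = n_draws,
                             seed = seed)
        tibble::tibble(country_id, stratum, year, estimate,
                       ci_low = ci$ci_low, ci_high = ci$ci_high, basis)
      } else {
        rg <- covariates$who_region[covariates$country_id == country_id]
        w <- pi_w[[rg]]
        tibble::tibble(country_id, stratum, year, estimate,
                       ci_low = truncate01(estimate - w / 2),
                       ci_high = truncate01(estimate + w / 2), basis)
      }
    }) |> dplyr::bind_rows()
  })
  by_country <- combine_strata(by_stratum$urban, by_stratum$rural,
                               covariates)
  list(by_stratum = by_stratum, by_country = by_country, fits = fits)
}
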