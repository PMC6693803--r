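#' Fit the three-level Poisson model of HWWS on facility presence
#'
#' Models binary HWWS outcomes per potential-contact event with a log link
#' (modified Poisson, so the facility coefficient exponentiates to a
#' prevalence ratio), with random intercepts for household and study. The
#' reported robust covariance is the study-clustered sandwich of the
#' companion marginal (population-averaged) modified-Poisson fit, whose
#' slopes coincide with the conditional model under the log link. Records are
#' filtered to the requested event class, rows with unobservable facility
#' status are dropped (listwise deletion, count kept), and the analysis can
#' be restricted to adult handwashing occasions.
#'
#' If any facility or region stratum has all-equal outcomes (separation for
#' a log link), or the mixed fit fails, the model falls back to a
#' fixed-effects modified Poisson with study-clustered robust standard
#' errors, with a warning.
#'
#' @param records observation tibble: `study_id`, `country_id`,
#'   `who_region`, `household_id`, `person_role`, `event_class`,
#'   `facility_present`, `hwws`.
#' @param event_class `"faecal_contact"` or `"food_contact"`.
#' @param adults_only restrict to adult handwashing occasions.
#' @param nAGQ integration setting passed to [lme4::glmer()] (0 uses the
#'   faster penalized-least-squares step only).
#' @return a `conditional_fit` object: coefficients (log scale), robust and
#'   model-based covariance, variance components, counts, and the analysis
#'   data.
#' @export
fit_conditional_model <- function(records,
                                  event_class = "faecal_contact",
                                  adults_only = FALSE,
                                  nAGQ = 1L) {
  stopifnot(is.data.frame(records))
  dat <- dplyr::filter(records, .data$event_class == !!event_class)
  if (adults_only) dat <- dplyr::filter(dat, .data$person_role == "adult")
  n_input <- nrow(dat)
  dat <- dplyr::filter(dat, !is.na(.data$facility_present), !is.na(.data$hwws))
  n_deleted <- n_input - nrow(dat)
  if (dplyr::n_distinct(dat$study_id) < 2) {
    abort("Need at least 2 studies to separate study-level clustering.")
  }
  if (dplyr::n_distinct(dat$facility_present) < 2) {
    abort("Both facility strata must be represented.")
  }
  dat <- dat |>
    dplyr::mutate(
      who_region = factor(.data$who_region,
                          levels = intersect(WHO_REGIONS, .data$who_region)),
      household_key = paste(.data$study_id, .data$household_id, sep = ":")
    )

  # all-0 or all-1 outcomes within a facility or region stratum make the
  # log-link MLE diverge
  sep <- c(
    dat |> dplyr::group_by(.data$facility_present) |>
      dplyr::summarise(d = dplyr::n_distinct(.data$hwws),
                       .groups = "drop") |> dplyr::pull("d"),
    dat |> dplyr::group_by(.data$who_region) |>
      dplyr::summarise(d = dplyr::n_distinct(.data$hwws),
                       .groups = "drop") |> dplyr::pull("d")
  )
  separated <- any(sep < 2)

  rhs <- if (nlevels(dat$who_region) > 1) {
    "facility_present + who_region"
  } else {
    "facility_present"
  }
  method <- "mixed"
  model <- NULL
  if (!separated) {
    model <- tryCatch(
      suppressMessages(lme4::glmer(
        as.formula(paste("hwws ~", rhs,
                         "+ (1 | study_id) + (1 | household_key)")),
        data = dat, family = stats::poisson(link = "log"), nAGQ = nAGQ)),
      error = function(e) NULL)
  }
  if (is.null(model)) {
    warn(paste0("Mixed Poisson fit unavailable",
                if (separated) " (separated stratum)" else "",
                "; falling back to fixed-effects modified Poisson with ",
                "study-clustered robust SEs."))
    method <- "robust-glm"
    model <- stats::glm(as.formula(paste("hwws ~", rhs)), data = dat,
                        family = stats::poisson(link = "log"))
  }

  if (method == "mixed") {
    beta <- lme4::fixef(model)
    naive_vcov <- tryCatch(as.matrix(vcov(model)),
                           error = function(e) {
                             diag(length(beta)) * NA_real_
                           })
    vc <- as.data.frame(lme4::VarCorr(model))
    varcomp <- c(household = vc$vcov[vc$grp == "household_key"],
                 study = vc$vcov[vc$grp == "study_id"])
    # study-clustered robust covariance from the companion marginal
    # (population-averaged) modified-Poisson fit: for a log link the
    # marginal and conditional models share their slopes, so the
    # cluster-robust covariance of the marginal fit is the sandwich for
    # the fixed-effect contrasts of interest
    marginal <- stats::glm(as.formula(paste("hwws ~", rhs)), data = dat,
                           family = stats::poisson(link = "log"))
    robust_vcov <- sandwich::vcovCL(marginal, cluster = dat$study_id)
    if (anyNA(naive_vcov)) naive_vcov <- vcov(marginal)
  } else {
    beta <- coef(model)
    robust_vcov <- sandwich::vcovCL(model, cluster = dat$study_id)
    naive_vcov <- vcov(model)
    varcomp <- c(household = NA_real_, study = NA_real_)
  }
  dimnames(robust_vcov) <- dimnames(naive_vcov)
  # t reference distribution: region contrasts and the intercept are
  # study-level covariates and consume cluster degrees of freedom
  g <- dplyr::n_distinct(dat$study_id)
  df_t <- max(1, g - nlevels(dat$who_region))

  structure(
    list(coefficients = beta,
         robust_vcov = robust_vcov,
         naive_vcov = naive_vcov,
         varcomp = varcomp,
         df_t = df_t,
         method = method,
         model = model,
         event_class = event_class,
         adults_only = adults_only,
         regions = levels(dat$who_region),
         n_events = nrow(dat),
         n_households = dplyr::n_distinct(dat$household_key),
         n_studies = dplyr::n_distinct(dat$study_id),
         n_deleted = n_deleted,
         data = dat),
    class = "conditional_fit")
}

#' @export
print.conditional_fit <- function(x, ...) {
  pr <- prevalence_ratio(x)
  cat("Modified-Poisson model of HWWS on facility presence (",
      x$method, ")\n", sep = "")
  cat("  ", x$n_events, " events | ", x$n_households, " households | ",
      x$n_studies, " studies | ", x$n_deleted,
      " rows listwise-deleted\n", sep = "")
  cat(sprintf("  prevalence ratio %.2f (95%% CI %.2f, %.2f), p %s\n",
              pr$pr, pr$ci_low, pr$ci_high,
              format.pval(pr$p_value, digits = 2)))
  invisible(x)
}

#' Prevalence ratio of HWWS by facility presence
#'
#' `PR = exp(facility coefficient)` with a Wald CI on the log scale from the
#' study-clustered robust standard error. With few studies a normal
#' reference undercovers, so the critical value is from a t distribution
#' with `n_studies - p` degrees of freedom, `p` counting the study-level
#' fixed effects (intercept and region contrasts).
#'
#' @param fit a [fit_conditional_model()] result.
#' @return tibble: `pr`, `ci_low`, `ci_high`, `p_value`.
#' @export
prevalence_ratio <- function(fit) {
  stopifnot(inherits(fit, "conditional_fit"))
  b <- unname(fit$coefficients["facility_present"])
  se <- sqrt(fit$robust_vcov["facility_present", "facility_present"])
  tcrit <- qt(0.975, fit$df_t)
  tibble::tibble(
    pr = exp(b),
    ci_low = exp(b - tcrit * se),
    ci_high = exp(b + tcrit * se),
    p_value = if (se == 0) NA_real_ else 2 * stats::pt(-abs(b / se),
                                                       fit$df_t)
  )
}

# design row on the log scale for a region/facility combination
conditional_design_row <- function(fit, region, facility) {
  nm <- names(fit$coefficients)
  x <- setNames(numeric(length(nm)), nm)
  x["(Intercept)"] <- 1
  x["facility_present"] <- facility
  col <- paste0("who_region", region)
  if (col %in% nm) x[col] <- 1
  x
}

#' Adjusted regional HWWS prevalence by facility presence
#'
#' Predicted prevalence at the region's indicator value with random effects
#' at their central value (zero on the log scale):
#' `exp(intercept + region + facility * coefficient)`, capped at 1 with a
#' warning. The CI is delta-method on the log scale (robust covariance)
#' transformed to the prevalence scale.
#'
#' @param fit a [fit_conditional_model()] result.
#' @param region WHO region represented in the fitted data.
#' @param facility 0 or 1.
#' @return tibble: `who_region`, `facility`, `prevalence`, `ci_low`,
#'   `ci_high`.
#' @export
predict_regional_prevalence <- function(fit, region, facility) {
  stopifnot(inherits(fit, "conditional_fit"), facility %in% c(0, 1))
  if (!region %in% fit$regions) {
    abort(paste0("Region ", region, " is not represented in the fitted ",
                 "data; use pooled_average_prediction()."))
  }
  x <- conditional_design_row(fit, region, facility)
  eta <- sum(x * fit$coefficients)
  se <- sqrt(drop(t(x) %*% fit$robust_vcov %*% x))
  tcrit <- qt(0.975, fit$df_t)
  prev <- exp(eta)
  if (prev > 1) {
    warn(sprintf("Predicted prevalence %.3f for %s capped at 1.", prev,
                 region))
    prev <- 1
  }
  tibble::tibble(who_region = region, facility = facility,
                 prevalence = prev,
                 ci_low = truncate01(exp(eta - tcrit * se)),
                 ci_high = truncate01(exp(eta + tcrit * se)))
}

# per-country adjusted prevalences (study random intercepts included,
# averaged over studies within country)
country_adjusted_prevalences <- function(fit, facility) {
  studies <- fit$data |>
    dplyr::distinct(.data$study_id, .data$country_id, .data$who_region)
  b_s <- if (fit$method == "mixed") {
    re <- lme4::ranef(fit$model)$study_id
    setNames(re[["(Intercept)"]], rownames(re))
  } else {
    setNames(rep(0, nrow(studies)), studies$study_id)
  }
  studies |>
    dplyr::mutate(prev = purrr::map2_dbl(
      .data$who_region, .data$study_id,
      function(rg, sid) {
        eta <- sum(conditional_design_row(fit, rg, facility) *
                     fit$coefficients) + b_s[[sid]]
        min(exp(eta), 1)
      })) |>
    dplyr::group_by(.data$country_id) |>
    dplyr::summarise(prev = mean(.data$prev), .groups = "drop")
}

#' Pooled-average HWWS prediction for unrepresented regions
#'
#' Regions without any contributing study receive the mean of the
#' country-level adjusted prevalences, with a 95% prediction interval
#' approximated as mean `+/- 1.96 * SD` of those country-level values,
#' truncated to `[0, 1]`.
#'
#' @param fit a [fit_conditional_model()] result.
#' @param region the unrepresented WHO region (labelling only).
#' @param facility 0 or 1.
#' @return tibble: `who_region`, `facility`, `prevalence`, `ci_low`,
#'   `ci_high`.
#' @export
pooled_average_prediction <- function(fit, region, facility) {
  stopifnot(inherits(fit, "conditional_fit"), facility %in% c(0, 1))
  cp <- country_adjusted_prevalences(fit, facility)
  if (nrow(cp) < 2) {
    abort("Need at least 2 represented countries for a pooled average.")
  }
  m <- mean(cp$prev)
  s <- sd(cp$prev)
  tibble::tibble(who_region = region, facility = facility,
                 prevalence = m,
                 ci_low = truncate01(m - qnorm(0.975) * s),
                 ci_high = truncate01(m + qnorm(0.975) * s))
}

#' Regional conditional-prevalence table
#'
#' Builds the per-region table of predicted HWWS prevalence with and without
#' a designated facility for the given LMI regions: region-specific adjusted
#' predictions where a region contributed data, pooled-average predictions
#' elsewhere, with a provenance flag.
#'
#' @param fit a [fit_conditional_model()] result.
#' @param regions WHO regions to tabulate (default all six).
#' @return tibble: `who_region`, `facility`, `prevalence`, `ci_low`,
#'   `ci_high`, `provenance`.
#' @export
regional_prevalence_table <- function(fit, regions = WHO_REGIONS) {
  purrr::map(regions, function(rg) {
    purrr::map(c(0, 1), function(f) {
      if (rg %in% fit$regions) {
        predict_regional_prevalence(fit, rg, f) |>
          dplyr::mutate(provenance = "region-specific")
      } else {
        pooled_average_prediction(fit, rg, f) |>
          dplyr::mutate(provenance = "pooled-average")
      }
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
}

#' Descriptive summary of pooled observation data
#'
#' Crude totals and prevalences overall and by facility stratum, for each
#' event class and for the adult-only restriction, plus the listwise
#' deletion count for unobservable facility status.
#'
#' @param records observation tibble.
#' @return tibble: `subset`, `event_class`, `facility`, `n_events`,
#'   `n_hwws`, `prevalence`; attribute `n_missing_facility`.
#' @export
describe_pooled_data <- function(records) {
  n_missing <- sum(is.na(records$facility_present))
  dat <- dplyr::filter(records, !is.na(.data$facility_present))
  one <- function(d, subset_label) {
    if (nrow(d) == 0) {
      return(tibble::tibble(subset = subset_label,
                            event_class = NA_character_,
                            facility = "all", n_events = 0L,
                            n_hwws = 0L, prevalence = NA_real_))
    }
    strata <- d |>
      dplyr::group_by(.data$event_class,
                      facility = as.character(.data$facility_present)) |>
      dplyr::summarise(n_events = dplyr::n(),
                       n_hwws = sum(.data$hwws), .groups = "drop")
    overall <- d |>
      dplyr::group_by(.data$event_class) |>
      dplyr::summarise(facility = "all", n_events = dplyr::n(),
                       n_hwws = sum(.data$hwws), .groups = "drop")
    dplyr::bind_rows(overall, strata) |>
      dplyr::mutate(subset = subset_label,
                    prevalence = .data$n_hwws / .data$n_events)
  }
  dplyr::bind_rows(
    one(dat, "all"),
    one(dplyr::filter(dat, .data$person_role == "adult"), "adults")
  ) |>
    dplyr::select("subset", "event_class", "facility", "n_events",
                  "n_hwws", "prevalence") |>
    structure(n_missing_facility = n_missing)
}
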