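#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the fixed effects of a facility-model fit
#'
#' @param x a `facility_fit`.
#' @param ... unused.
#' @return tibble: `term`, `estimate`, `std.error`.
#' @method tidy facility_fit
#' @export
tidy.facility_fit <- function(x, ...) {
  tibble::tibble(term = names(x$fixed_effects),
                 estimate = unname(x$fixed_effects),
                 std.error = sqrt(diag(x$vcov_fixed)))
}

#' One-row summary of a facility-model fit
#'
#' @param x a `facility_fit`.
#' @param ... unused.
#' @return tibble with variance components and data sizes.
#' @method glance facility_fit
#' @export
glance.facility_fit <- function(x, ...) {
  tibble::tibble(stratum = x$stratum,
                 sigma2_country = x$sigma2_country,
                 sigma2_resid = x$sigma2_resid,
                 year_center = x$year_center,
                 nobs = x$n_points,
                 n_countries = x$n_countries,
                 n_clamped = x$n_clamped)
}

#' Tidy the coefficients of a conditional-prevalence fit
#'
#' Log-scale coefficients with robust (study-clustered) standard errors and
#' the exponentiated prevalence-ratio scale.
#'
#' @param x a `conditional_fit`.
#' @param ... unused.
#' @return tibble: `term`, `estimate`, `std.error`, `statistic`, `p.value`,
#'   `ratio`.
#' @method tidy conditional_fit
#' @export
tidy.conditional_fit <- function(x, ...) {
  se <- sqrt(diag(x$robust_vcov))
  z <- x$coefficients / se
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients),
                 std.error = unname(se),
                 statistic = unname(z),
                 p.value = unname(2 * pnorm(-abs(z))),
                 ratio = exp(unname(x$coefficients)))
}

#' One-row summary of a conditional-prevalence fit
#'
#' @param x a `conditional_fit`.
#' @param ... unused.
#' @return tibble with data sizes, variance components and the fit method.
#' @method glance conditional_fit
#' @export
glance.conditional_fit <- function(x, ...) {
  tibble::tibble(method = x$method,
                 n_events = x$n_events,
                 n_households = x$n_households,
                 n_studies = x$n_studies,
                 n_deleted = x$n_deleted,
                 var_household = unname(x$varcomp["household"]),
                 var_study = unname(x$varcomp["study"]))
}

#' Per-study table of a meta-analysis
#'
#' @param x a `meta_result`.
#' @param ... unused.
#' @return the per-study tibble with proportions, variances and normalized
#'   random-effects weights.
#' @method tidy meta_result
#' @export
tidy.meta_result <- function(x, ...) {
  x$studies
}

#' One-row summary of a meta-analysis
#'
#' @param x a `meta_result`.
#' @param ... unused.
#' @return tibble: `pooled`, `ci_low`, `ci_high`, `tau2`, `Q`, `df`, `I2`,
#'   `n_studies`, `scale`.
#' @method glance meta_result
#' @export
glance.meta_result <- function(x, ...) {
  tibble::tibble(pooled = x$pooled, ci_low = x$ci_low, ci_high = x$ci_high,
                 tau2 = x$tau2, Q = x$Q, df = x$df, I2 = x$I2,
                 n_studies = nrow(x$studies), scale = x$scale)
}
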