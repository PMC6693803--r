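#' Combine facility presence with conditional prevalences
#'
#' The HWWS prevalence after potential faecal contact is the mixture
#' `p_given_hw * p_hw + p_given_nohw * (1 - p_hw)`: the conditional
#' prevalence with a designated facility weighted by facility presence,
#' plus the conditional prevalence without one weighted by its complement.
#'
#' @param p_hw proportion of the population with a designated handwashing
#'   facility.
#' @param p_given_hw HWWS prevalence given a facility is present.
#' @param p_given_nohw HWWS prevalence given no facility.
#' @return numeric vector of combined prevalences (vectorized over inputs).
#' @export
combine_eq1 <- function(p_hw, p_given_hw, p_given_nohw) {
  assert_prob(p_hw, "p_hw")
  assert_prob(p_given_hw, "p_given_hw")
  assert_prob(p_given_nohw, "p_given_nohw")
  p_given_hw * p_hw + p_given_nohw * (1 - p_hw)
}

# first-order (delta-method) SE of the mixture, inputs independent
eq1_se <- function(p_hw, p_given_hw, p_given_nohw,
                   se_hw, se_given_hw, se_given_nohw) {
  sqrt((p_given_hw - p_given_nohw)^2 * se_hw^2 +
         p_hw^2 * se_given_hw^2 +
         (1 - p_hw)^2 * se_given_nohw^2)
}

#' Country-level HWWS estimates after potential faecal contact
#'
#' Low- and middle-income countries combine their modelled facility
#' presence with their region's conditional prevalences through the mixture
#' formula; high-income countries are assigned the pooled meta-analytic
#' HWWS prevalence directly. The regional conditional-prevalence errors
#' enter each country's CI undiminished (a projection from regional to
#' country level widens intervals), and are tracked separately from the
#' country-specific facility-presence error so aggregation can treat them
#' as fully correlated within a region.
#'
#' @param facility_estimates tibble of combined country facility estimates
#'   (`country_id`, `estimate`, `ci_low`, `ci_high`; from
#'   [combine_strata()]), carrying or joinable to `who_region` and
#'   `income_group`.
#' @param conditional_prevalences regional table from
#'   [regional_prevalence_table()].
#' @param hic_pooled a [pool_random_effects()] result for the high-income
#'   studies.
#' @param covariates optional covariate tibble supplying `who_region` and
#'   `income_group` when `facility_estimates` lacks them.
#' @param year reporting year recorded on the output.
#' @return tibble: `country_id`, `scope`, `year`, `prevalence`, `ci_low`,
#'   `ci_high`, `method`, plus the error decomposition (`se_shared`,
#'   `se_indep`, `shared_group`) used by [aggregate_hwws()].
#' @export
country_hwws_estimates <- function(facility_estimates,
                                   conditional_prevalences,
                                   hic_pooled,
                                   covariates = NULL,
                                   year = 2015) {
  fe <- facility_estimates
  if (!is.null(covariates)) {
    fe <- dplyr::inner_join(
      fe, dplyr::select(covariates, "country_id", "who_region",
                        "income_group"),
      by = "country_id")
  }
  stopifnot(all(c("who_region", "income_group") %in% names(fe)),
            inherits(hic_pooled, "meta_result"))
  cond <- conditional_prevalences |>
    dplyr::mutate(se = se_from_ci(.data$ci_low, .data$ci_high)) |>
    dplyr::select("who_region", "facility", "prevalence", "se") |>
    tidyr::pivot_wider(names_from = "facility",
                       values_from = c("prevalence", "se"))

  missing_reg <- setdiff(fe$who_region[fe$income_group != "high"],
                         cond$who_region)
  if (length(missing_reg)) {
    bad <- fe$country_id[fe$who_region %in% missing_reg &
                           fe$income_group != "high"]
    abort(paste0("No conditional prevalences for region(s) ",
                 paste(missing_reg, collapse = ", "), " (countries ",
                 paste(head(bad, 5), collapse = ", "), " ...)."))
  }

  fe |>
    dplyr::left_join(cond, by = "who_region") |>
    dplyr::mutate(
      se_hw = se_from_ci(.data$ci_low, .data$ci_high),
      hic = .data$income_group == "high",
      prevalence = ifelse(.data$hic, hic_pooled$pooled,
                          combine_eq1(.data$estimate,
                                      dplyr::coalesce(.data$prevalence_1, 0),
                                      dplyr::coalesce(.data$prevalence_0,
                                                      0))),
      se_shared = ifelse(.data$hic, hic_pooled$se,
                         sqrt(.data$estimate^2 * .data$se_1^2 +
                                (1 - .data$estimate)^2 * .data$se_0^2)),
      se_indep = ifelse(.data$hic, 0,
                        abs(.data$prevalence_1 - .data$prevalence_0) *
                          .data$se_hw),
      se_total = sqrt(.data$se_shared^2 + .data$se_indep^2),
      shared_group = ifelse(.data$hic, "HIC", .data$who_region),
      method = ifelse(.data$hic, "meta-direct", "eq1"),
      scope = "country",
      year = year,
      hwws_ci_low = truncate01(.data$prevalence -
                                 qnorm(0.975) * .data$se_total),
      hwws_ci_high = truncate01(.data$prevalence +
                                  qnorm(0.975) * .data$se_total)
    ) |>
    dplyr::select("country_id", "scope", "year", "who_region",
                  "income_group", "prevalence",
                  ci_low = "hwws_ci_low", ci_high = "hwws_ci_high",
                  "method", "se_shared", "se_indep", "shared_group")
}

#' Population-weighted aggregation of country HWWS estimates
#'
#' Aggregates country HWWS estimates to regional, income-class or world
#' level as population-weighted means. Standard errors honour the error
#' structure of the country estimates: the regional conditional-prevalence
#' error is shared (fully correlated) among countries of one region, so
#' its weighted SDs add linearly within a region, while facility-presence
#' errors are independent across countries and their variances add in
#' quadrature.
#'
#' @param country_estimates output of [country_hwws_estimates()].
#' @param populations tibble: `country_id`, `population` (persons; faecal
#'   contacts are assumed to scale with persons at equal rates everywhere).
#' @param grouping one of `"region_income"`, `"income"`, `"world"`.
#' @return tibble: `group`, `prevalence`, `ci_low`, `ci_high`,
#'   `n_countries`.
#' @export
aggregate_hwws <- function(country_estimates, populations,
                           grouping = c("region_income", "income",
                                        "world")) {
  grouping <- match.arg(grouping)
  dat <- dplyr::inner_join(country_estimates, populations,
                           by = "country_id") |>
    dplyr::mutate(
      income_class = ifelse(.data$income_group == "high", "HIC", "LMI"),
      group = switch(grouping,
                     region_income = paste(.data$who_region,
                                           .data$income_class),
                     income = .data$income_class,
                     world = "World"))
  if (nrow(dat) == 0) abort("Empty group: no countries to aggregate.")
  dat |>
    dplyr::group_by(.data$group) |>
    dplyr::group_map(function(d, key) {
      w <- d$population / sum(d$population)
      var_shared <- d |>
        dplyr::mutate(w = w) |>
        dplyr::group_by(.data$shared_group) |>
        dplyr::summarise(s = sum(.data$w * .data$se_shared),
                         .groups = "drop") |>
        dplyr::summarise(v = sum(.data$s^2)) |>
        dplyr::pull("v")
      se <- sqrt(var_shared + sum(w^2 * d$se_indep^2))
      est <- sum(w * d$prevalence)
      tibble::tibble(group = key$group, prevalence = est,
                     ci_low = truncate01(est - qnorm(0.975) * se),
                     ci_high = truncate01(est + qnorm(0.975) * se),
                     n_countries = nrow(d))
    }) |>
    dplyr::bind_rows()
}

#' High-income sensitivity analysis via the combination formula
#'
#' Instead of assigning high-income countries the pooled meta-analytic
#' prevalence directly, applies the mixture formula with the modelled
#' high-income facility presence, the pooled prevalence as the
#' with-facility value, and the arithmetic mean of the low- and
#' middle-income regional without-facility prevalences as the
#' without-facility value.
#'
#' @param hic_facility high-income facility-presence proportion.
#' @param hic_pooled pooled meta-analytic HWWS proportion.
#' @param lmi_no_facility_values numeric vector of regional
#'   without-facility prevalences.
#' @return single combined prevalence (fraction).
#' @export
sensitivity_hic_eq1 <- function(hic_facility, hic_pooled,
                                lmi_no_facility_values) {
  if (length(lmi_no_facility_values) == 0) {
    abort("`lmi_no_facility_values` must not be empty.")
  }
  assert_prob(lmi_no_facility_values, "lmi_no_facility_values")
  combine_eq1(hic_facility, hic_pooled, mean(lmi_no_facility_values))
}
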