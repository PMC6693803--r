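#' Configuration for the synthetic survey-point generator
#'
#' Describes a world of countries (distributed over WHO regions and income
#' groups) and a sparse pattern of national survey points on the proportion
#' of households with a designated handwashing facility. The default pattern
#' reproduces the sparsity of the compiled survey record: of 194 countries,
#' 117 have no survey point, 48 have one, 23 have two, and a handful more.
#'
#' Survey noise is added on the logit scale, consistent with the transform
#' the analysis model applies, and urban and rural series are generated with
#' separate coefficient sets.
#'
#' @param n_countries_per_region_income data frame with columns `who_region`,
#'   `income_group`, `n`: number of countries per cell. Default: 194
#'   countries spread over the six WHO regions and four income groups.
#' @param data_pattern named numeric vector: relative frequency of countries
#'   having 0, 1, 2, ... survey points (names are the counts).
#' @param year_range integer vector `c(first, last)` of admissible survey
#'   years.
#' @param true_coefficients list with elements `urban` and `rural`, each a
#'   list with `intercept`, `year_slope` (logit units per year, year centred
#'   at the mid-range), `region` (named offsets for AMR/EMR/EUR/SEAR/WPR
#'   relative to AFR) and `income` (named offsets for lower-middle,
#'   upper-middle, high relative to low).
#' @param sigma_country SD of country random intercepts (logit scale).
#' @param sigma_resid residual SD of survey points (logit scale).
#' @param income_data_weights named weights governing which income groups
#'   the surveyed countries come from. The compiled survey record draws
#'   almost exclusively on low- and middle-income countries (a single
#'   high-income country contributed data), so the default strongly
#'   down-weights high-income countries while guaranteeing one high-income
#'   recipient; the marginal points-per-country distribution is unchanged.
#' @param seed integer seed driving the generator.
#' @return a `survey_gen_config` list.
#' @export
survey_gen_config <- function(n_countries_per_region_income = NULL,
                              data_pattern = c(`0` = 117, `1` = 48, `2` = 23,
                                               `3` = 4, `4` = 1, `5` = 1),
                              year_range = c(2000L, 2016L),
                              true_coefficients = NULL,
                              sigma_country = 0.7,
                              sigma_resid = 0.4,
                              income_data_weights = c(
                                low = 1, `lower-middle` = 1,
                                `upper-middle` = 1, high = 0.02),
                              seed = 1L) {
  if (is.null(n_countries_per_region_income)) {
    n_countries_per_region_income <- default_country_table()
  }
  if (is.null(true_coefficients)) {
    true_coefficients <- default_survey_coefficients()
  }
  stopifnot(sigma_country >= 0, sigma_resid >= 0,
            length(year_range) == 2, year_range[2] >= year_range[1])
  for (str in c("urban", "rural")) {
    co <- true_coefficients[[str]]
    vals <- c(co$intercept, co$year_slope, co$region, co$income)
    if (any(!is.finite(vals))) {
      abort("`true_coefficients` must be finite.")
    }
  }
  if (any(data_pattern < 0) || sum(data_pattern) <= 0) {
    abort("`data_pattern` must be non-negative with positive total.")
  }
  stopifnot(all(INCOME_GROUPS %in% names(income_data_weights)),
            all(income_data_weights >= 0))
  structure(
    list(n_countries_per_region_income = n_countries_per_region_income,
         data_pattern = data_pattern,
         year_range = as.integer(year_range),
         true_coefficients = true_coefficients,
         sigma_country = sigma_country,
         sigma_resid = sigma_resid,
         income_data_weights = income_data_weights,
         seed = as.integer(seed)),
    class = "survey_gen_config")
}

# 194 countries over region x income cells, roughly matching the world's
# composition (AFR mostly low/lower-middle, EUR mostly high, ...)
default_country_table <- function() {
  tibble::tribble(
    ~who_region, ~low, ~`lower-middle`, ~`upper-middle`, ~high,
    "AFR",        26L,  14L,              6L,              1L,
    "AMR",         1L,   4L,             16L,             14L,
    "EMR",         2L,   9L,              4L,              7L,
    "EUR",         0L,   4L,             13L,             36L,
    "SEAR",        1L,   7L,              3L,              0L,
    "WPR",         0L,   8L,              8L,             10L
  ) |>
    tidyr::pivot_longer(-"who_region", names_to = "income_group",
                        values_to = "n") |>
    dplyr::filter(.data$n > 0)
}

default_survey_coefficients <- function() {
  region <- c(AMR = 2.5, EMR = 1.8, EUR = 3.0, SEAR = 1.5, WPR = 2.2)
  income <- c(`lower-middle` = 0.8, `upper-middle` = 1.6, high = 3.0)
  list(
    urban = list(intercept = qlogis(0.25), year_slope = 0.02,
                 region = region, income = income),
    rural = list(intercept = qlogis(0.12), year_slope = 0.025,
                 region = region + 0.2, income = income)
  )
}

# fixed-part linear predictor of the generating model
synth_survey_eta <- function(co, year, year_center, who_region, income_group) {
  reg <- c(AFR = 0, co$region)[who_region]
  inc <- c(low = 0, co$income)[income_group]
  co$intercept + co$year_slope * (year - year_center) + reg + inc
}

#' Generate synthetic national survey points on facility presence
#'
#' Emits a sparse country-year-stratum table of survey proportions with the
#' statistical structure the facility model assumes: a logit-linear fixed
#' part in year, WHO region and income group, a country random intercept,
#' and residual noise, all on the logit scale. Countries without survey
#' points are still emitted in the covariate table so downstream
#' extrapolation is exercised.
#'
#' @param config a [survey_gen_config()].
#' @return list with `points` (tibble: `country_id`, `year`, `stratum`,
#'   `proportion`, `source`), `covariates` (tibble: `country_id`,
#'   `who_region`, `income_group`, `pop_urban`, `pop_rural`) and `truth`
#'   (generating coefficients, random intercepts and the centring year).
#' @export
generate_survey_points <- function(config) {
  stopifnot(inherits(config, "survey_gen_config"))
  with_local_seed(config$seed, {
    cells <- config$n_countries_per_region_income
    covariates <- cells |>
      dplyr::rowwise() |>
      dplyr::reframe(who_region = .data$who_region,
                     income_group = .data$income_group,
                     idx = seq_len(.data$n)) |>
      dplyr::mutate(
        country_id = sprintf("C%03d", dplyr::row_number()),
        pop_urban = rlnorm(dplyr::n(), meanlog = 14.5, sdlog = 1.3),
        pop_rural = rlnorm(dplyr::n(), meanlog = 14.2, sdlog = 1.4)
      ) |>
      dplyr::select("country_id", "who_region", "income_group",
                    "pop_urban", "pop_rural")

    n_country <- nrow(covariates)
    counts <- as.integer(names(config$data_pattern))
    n_points <- counts[sample.int(length(counts), n_country, replace = TRUE,
                                  prob = config$data_pattern /
                                    sum(config$data_pattern))]
    # reassign which countries hold the positive point counts so that
    # surveyed countries are drawn with income-dependent weights (the
    # marginal points-per-country distribution is preserved)
    pos <- n_points[n_points > 0]
    if (length(pos) > 0 && length(pos) < n_country) {
      wt <- config$income_data_weights[covariates$income_group]
      if (any(wt > 0)) {
        recipients <- sample.int(n_country, length(pos),
                                 prob = pmax(wt, 1e-12))
        hic_idx <- which(covariates$income_group == "high")
        if (length(hic_idx) && !any(recipients %in% hic_idx)) {
          recipients[sample.int(length(recipients), 1)] <-
            sample(hic_idx, 1)
        }
        n_points <- integer(n_country)
        n_points[recipients] <- sample(pos)
      }
    }
    year_center <- mean(config$year_range)
    years_avail <- seq(config$year_range[1], config$year_range[2])

    ranef <- list(
      urban = rnorm(n_country, 0, config$sigma_country),
      rural = rnorm(n_country, 0, config$sigma_country)
    )

    rows <- purrr::map(seq_len(n_country), function(i) {
      k <- n_points[i]
      if (k == 0) return(NULL)
      yrs <- sort(sample(years_avail, k))
      purrr::map(c("urban", "rural"), function(str) {
        co <- config$true_coefficients[[str]]
        eta <- synth_survey_eta(co, yrs, year_center,
                                covariates$who_region[i],
                                covariates$income_group[i]) +
          ranef[[str]][i] + rnorm(k, 0, config$sigma_resid)
        tibble::tibble(country_id = covariates$country_id[i],
                       year = yrs, stratum = str,
                       proportion = plogis(pmin(pmax(eta, -30), 30)),
                       source = "synthetic")
      }) |> dplyr::bind_rows()
    }) |> dplyr::bind_rows()

    list(points = rows,
         covariates = covariates,
         truth = list(coefficients = config$true_coefficients,
                      year_center = year_center,
                      random_intercepts = tibble::tibble(
                        country_id = covariates$country_id,
                        urban = ranef$urban, rural = ranef$rural),
                      sigma_country = config$sigma_country,
                      sigma_resid = config$sigma_resid,
                      n_points = n_points))
  })
}

#' Configuration for the synthetic structured-observation generator
#'
#' Emulates pooled structured-observation datasets: studies of households,
#' households with binary facility presence, and per-event binary
#' handwashing-with-soap outcomes generated on the log-risk scale
#' (multiplicative prevalence ratio), matching the log-link analysis model.
#'
#' @param n_studies number of studies.
#' @param study_regions character vector (length `n_studies`) of WHO regions;
#'   default mirrors the composition of the nine pooled datasets (five AFR,
#'   one AMR, two SEAR, one WPR).
#' @param n_households households per study (scalar or length `n_studies`).
#' @param events_per_household mean of the Poisson number of potential
#'   faecal-contact events per household.
#' @param true_pr prevalence ratio of HWWS, facility present vs absent.
#' @param baseline_prev_by_region named vector: HWWS prevalence without a
#'   facility, by region.
#' @param p_facility probability a household has a designated facility.
#' @param sigma_household,sigma_study random-intercept SDs on the log-risk
#'   scale.
#' @param adult_fraction probability an event involves an adult.
#' @param truncate if `TRUE` (default) event probabilities are truncated at
#'   0.99; if `FALSE`, any implied probability above 1 is an error.
#' @param seed integer seed.
#' @return an `obs_gen_config` list.
#' @export
obs_gen_config <- function(n_studies = 9L,
                           study_regions = c(rep("AFR", 5), "AMR",
                                             "SEAR", "SEAR", "WPR"),
                           n_households = 200L,
                           events_per_household = 2.2,
                           true_pr = 2,
                           baseline_prev_by_region = c(AFR = 0.071,
                                                       AMR = 0.198,
                                                       EMR = 0.128,
                                                       EUR = 0.128,
                                                       SEAR = 0.163,
                                                       WPR = 0.090),
                           p_facility = 0.35,
                           sigma_household = 0.5,
                           sigma_study = 0.3,
                           adult_fraction = 0.65,
                           truncate = TRUE,
                           seed = 1L) {
  stopifnot(n_studies >= 1, length(study_regions) == n_studies,
            sigma_household >= 0, sigma_study >= 0,
            p_facility >= 0, p_facility <= 1,
            adult_fraction >= 0, adult_fraction <= 1)
  if (true_pr <= 0) abort("`true_pr` must be positive.")
  used <- baseline_prev_by_region[unique(study_regions)]
  if (anyNA(used) || any(used <= 0 | used >= 1)) {
    abort("baseline prevalences must be in (0, 1) for every study region.")
  }
  if (true_pr * max(used) > 1 && !truncate) {
    abort("true_pr x max baseline exceeds 1 with truncation disabled.")
  }
  structure(
    list(n_studies = as.integer(n_studies), study_regions = study_regions,
         n_households = rep_len(as.integer(n_households), n_studies),
         events_per_household = events_per_household,
         true_pr = true_pr,
         baseline_prev_by_region = baseline_prev_by_region,
         p_facility = p_facility,
         sigma_household = sigma_household, sigma_study = sigma_study,
         adult_fraction = adult_fraction, truncate = truncate,
         seed = as.integer(seed)),
    class = "obs_gen_config")
}

#' Generate a synthetic pooled structured-observation dataset
#'
#' Event-level HWWS outcomes are Bernoulli with mean
#' `baseline * PR^facility * exp(b_study + b_household)`, truncated at 0.99,
#' so that parameter recovery by the log-link analysis model is a fair test.
#'
#' @param config an [obs_gen_config()].
#' @return list with `records` (tibble: `study_id`, `country_id`,
#'   `who_region`, `household_id`, `person_role`, `event_class`,
#'   `facility_present`, `hwws`) and `truth`.
#' @export
generate_observation_study <- function(config) {
  stopifnot(inherits(config, "obs_gen_config"))
  with_local_seed(config$seed, {
    studies <- purrr::map(seq_len(config$n_studies), function(s) {
      region <- config$study_regions[s]
      nh <- config$n_households[s]
      b_s <- rnorm(1, 0, config$sigma_study)
      b_h <- rnorm(nh, 0, config$sigma_household)
      fac <- rbinom(nh, 1, config$p_facility)
      n_ev <- rpois(nh, config$events_per_household)
      hh <- rep(seq_len(nh), n_ev)
      if (length(hh) == 0) return(NULL)
      base <- config$baseline_prev_by_region[[region]]
      p <- base * config$true_pr^fac[hh] * exp(b_s + b_h[hh])
      if (config$truncate) {
        p <- pmin(p, 0.99)
      } else if (any(p > 1)) {
        abort("implied event probability exceeds 1 with truncation disabled.")
      }
      tibble::tibble(
        study_id = sprintf("S%02d", s),
        country_id = sprintf("OC%02d", s),
        who_region = region,
        household_id = sprintf("S%02d-H%04d", s, hh),
        person_role = ifelse(runif(length(hh)) < config$adult_fraction,
                             "adult", "child"),
        event_class = "faecal_contact",
        facility_present = fac[hh],
        hwws = rbinom(length(hh), 1, p)
      )
    })
    records <- dplyr::bind_rows(studies)
    list(records = records,
         truth = list(pr = config$true_pr,
                      baseline_prev_by_region = config$baseline_prev_by_region,
                      p_facility = config$p_facility,
                      sigma_household = config$sigma_household,
                      sigma_study = config$sigma_study))
  })
}

#' Configuration for the synthetic high-income meta-analysis generator
#'
#' Emulates study-level summaries of observed HWWS after potential faecal
#' contact in high-income countries: each study's underlying proportion is
#' inverse-logit of `logit(true_mean_prop) + N(0, tau^2)`, and observed
#' counts are binomial at the study size. Large sizes and non-zero `tau`
#' yield the extreme heterogeneity characteristic of such pooled
#' observational series.
#'
#' @param n_studies number of studies (default 15).
#' @param true_mean_prop mean proportion on the logit scale centre.
#' @param tau between-study SD on the logit scale.
#' @param size_range integer range of events per study.
#' @param seed integer seed.
#' @return a `meta_gen_config` list.
#' @export
meta_gen_config <- function(n_studies = 15L, true_mean_prop = 0.5,
                            tau = 1.0, size_range = c(100L, 2000L),
                            seed = 1L) {
  stopifnot(n_studies >= 2, true_mean_prop > 0, true_mean_prop < 1,
            tau >= 0, length(size_range) == 2, size_range[1] >= 1)
  structure(list(n_studies = as.integer(n_studies),
                 true_mean_prop = true_mean_prop, tau = tau,
                 size_range = as.integer(size_range),
                 seed = as.integer(seed)),
            class = "meta_gen_config")
}

#' Generate synthetic study summaries for meta-analysis
#'
#' @param config a [meta_gen_config()].
#' @return list with `studies` (tibble: `study_id`, `country_id`,
#'   `who_region`, `setting`, `n_events`, `n_hwws`) and `truth`.
#' @export
generate_meta_studies <- function(config) {
  stopifnot(inherits(config, "meta_gen_config"))
  with_local_seed(config$seed, {
    n <- config$n_studies
    p_i <- plogis(qlogis(config$true_mean_prop) + rnorm(n, 0, config$tau))
    n_events <- sample(seq(config$size_range[1], config$size_range[2]),
                       n, replace = TRUE)
    studies <- tibble::tibble(
      study_id = sprintf("M%02d", seq_len(n)),
      country_id = sprintf("HC%02d", seq_len(n)),
      who_region = rep_len(c("AMR", "EUR", "WPR"), n),
      setting = rep_len(c("public", "household"), n),
      n_events = n_events,
      n_hwws = rbinom(n, n_events, p_i)
    )
    list(studies = studies,
         truth = list(true_mean_prop = config$true_mean_prop,
                      tau = config$tau, p_i = p_i))
  })
}
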