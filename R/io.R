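#' Read a survey-points file
#'
#' Delimited text with columns `country_id`, `year`, `stratum`,
#' `proportion` and optionally `iso3` and `source`.
#'
#' @param path file path.
#' @param delim field delimiter (default tab; `","` for CSV).
#' @return tibble of survey points.
#' @export
read_survey_points <- function(path, delim = "\t") {
  check_file(path)
  out <- readr::read_delim(path, delim = delim, show_col_types = FALSE)
  require_columns(out, c("country_id", "year", "stratum", "proportion"),
                  path)
  out
}

#' Read a country-covariates file
#'
#' Columns: `country_id`, `who_region`, `income_group`, `pop_urban`,
#' `pop_rural`.
#'
#' @inheritParams read_survey_points
#' @return tibble of covariates.
#' @export
read_covariates <- function(path, delim = "\t") {
  check_file(path)
  out <- readr::read_delim(path, delim = delim, show_col_types = FALSE)
  require_columns(out, c("country_id", "who_region", "income_group",
                         "pop_urban", "pop_rural"), path)
  out
}

#' Read a structured-observation file
#'
#' Columns: `study_id`, `country_id`, `who_region`, `household_id`,
#' `person_role`, `event_class`, `facility_present`, `hwws`. Blank
#' `facility_present` values trigger listwise deletion downstream with an
#' audited count.
#'
#' @inheritParams read_survey_points
#' @return tibble of observation records.
#' @export
read_observations <- function(path, delim = "\t") {
  check_file(path)
  out <- readr::read_delim(path, delim = delim, show_col_types = FALSE)
  require_columns(out, c("study_id", "country_id", "who_region",
                         "household_id", "person_role", "event_class",
                         "facility_present", "hwws"), path)
  out
}

#' Read a meta-analysis study-summary file
#'
#' Columns: `study_id`, `country_id`, `who_region`, `setting`, `n_events`,
#' `n_hwws`.
#'
#' @inheritParams read_survey_points
#' @return tibble of study summaries.
#' @export
read_meta_studies <- function(path, delim = "\t") {
  check_file(path)
  out <- readr::read_delim(path, delim = delim, show_col_types = FALSE)
  require_columns(out, c("study_id", "n_events", "n_hwws"), path)
  out
}

check_file <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Input file not found: ", path))
  }
  invisible(path)
}

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(paste0(path, " is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  invisible(df)
}

#' Published regional facility-presence estimates for 2015
#'
#' Reference summary table of the percentage of population with access to a
#' designated handwashing facility in 2015, by WHO region within income
#' class, stratum and income class, as published at the global level.
#' Shipped for desk-scale reproduction of the regional combination step.
#'
#' @return tibble: `area`, `estimate_pct`, `ci_low_pct`, `ci_high_pct`.
#' @export
published_facility_presence <- function() {
  readr::read_csv(system.file("extdata",
                              "published_facility_presence_2015.csv",
                              package = "handwashr", mustWork = TRUE),
                  show_col_types = FALSE)
}

#' Published conditional HWWS prevalences by region
#'
#' Reference summary table of predicted HWWS prevalence after potential
#' faecal contact with (`facility = 1`) and without (`facility = 0`) a
#' designated handwashing facility, by WHO region (LMI) plus the pooled
#' high-income value from meta-analysis.
#'
#' @return tibble: `area`, `facility`, `prevalence`, `ci_low`, `ci_high`,
#'   `source`.
#' @export
published_conditional_prevalence <- function() {
  readr::read_csv(system.file("extdata",
                              "published_conditional_prevalence.csv",
                              package = "handwashr", mustWork = TRUE),
                  show_col_types = FALSE, na = "NA")
}
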