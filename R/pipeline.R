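#' Pipeline run configuration
#'
#' Bundles inputs and settings for an end-to-end run. Inputs are either
#' file paths (delimited text, see the `read_*` readers) or in-memory
#' tibbles, or generator configurations for a fully synthetic run.
#'
#' @param survey_points,covariates,observations,meta_studies file path or
#'   tibble; all four may instead be `NULL` when the matching generator
#'   config is supplied.
#' @param survey_config,obs_config,meta_config generator configurations
#'   ([survey_gen_config()], [obs_gen_config()], [meta_gen_config()]) used
#'   when the corresponding input is `NULL`.
#' @param target_year reporting year (default 2015).
#' @param n_mc_draws Monte-Carlo draws per country CI (>= 100).
#' @param seed integer seed for all stochastic steps.
#' @param filter_post2009 drop survey points before 2009 (sensitivity).
#' @param hic_eq1_sensitivity also compute the high-income sensitivity
#'   analysis through the combination formula.
#' @param run_loo run leave-one-out cross-validation (refits the model once
#'   per country with a target-year point).
#' @param output_dir directory for report tables; `NULL` keeps results
#'   in memory only.
#' @return a `hwws_config` list.
#' @export
hwws_config <- function(survey_points = NULL, covariates = NULL,
                        observations = NULL, meta_studies = NULL,
                        survey_config = NULL, obs_config = NULL,
                        meta_config = NULL,
                        target_year = 2015, n_mc_draws = 10000,
                        seed = 1L, filter_post2009 = FALSE,
                        hic_eq1_sensitivity = TRUE,
                        run_loo = FALSE, output_dir = NULL) {
  if (n_mc_draws < 100) abort("`n_mc_draws` must be at least 100.")
  structure(
    list(survey_points = survey_points, covariates = covariates,
         observations = observations, meta_studies = meta_studies,
         survey_config = survey_config, obs_config = obs_config,
         meta_config = meta_config,
         target_year = target_year, n_mc_draws = n_mc_draws,
         seed = as.integer(seed), filter_post2009 = filter_post2009,
         hic_eq1_sensitivity = hic_eq1_sensitivity,
         run_loo = run_loo, output_dir = output_dir),
    class = "hwws_config")
}

load_input <- function(x, reader) {
  if (is.null(x)) return(NULL)
  if (is.data.frame(x)) return(tibble::as_tibble(x))
  reader(x)
}

resolve_inputs <- function(config) {
  points <- load_input(config$survey_points, read_survey_points)
  covariates <- load_input(config$covariates, read_covariates)
  if (is.null(points) || is.null(covariates)) {
    if (is.null(config$survey_config)) {
      abort("Either survey inputs or `survey_config` must be provided.")
    }
    gen <- generate_survey_points(config$survey_config)
    points <- points %||% gen$points
    covariates <- covariates %||% gen$covariates
  }
  records <- load_input(config$observations, read_observations)
  if (is.null(records)) {
    if (is.null(config$obs_config)) {
      abort("Either observation records or `obs_config` must be provided.")
    }
    records <- generate_observation_study(config$obs_config)$records
  }
  meta <- load_input(config$meta_studies, read_meta_studies)
  if (is.null(meta)) {
    if (is.null(config$meta_config)) {
      abort("Either meta studies or `meta_config` must be provided.")
    }
    meta <- generate_meta_studies(config$meta_config)$studies
  }
  list(points = points, covariates = covariates, records = records,
       meta = meta)
}

#' Validate pipeline inputs
#'
#' Schema, range and referential-integrity checks on the four input tables.
#' Violations are reported, not thrown, so a run can audit its inputs.
#'
#' @param config an [hwws_config()] (or a list as returned by the internal
#'   input resolver).
#' @return tibble of violations: `table`, `row`, `column`, `problem`
#'   (zero rows when all checks pass).
#' @export
validate_inputs <- function(config) {
  inputs <- if (inherits(config, "hwws_config")) {
    resolve_inputs(config)
  } else {
    config
  }
  v <- list()
  add <- function(tbl, rows, col, problem) {
    if (length(rows)) {
      v[[length(v) + 1]] <<- tibble::tibble(table = tbl, row = rows,
                                            column = col, problem = problem)
    }
  }
  p <- inputs$points
  add("survey_points", which(p$proportion < 0 | p$proportion > 1),
      "proportion", "outside [0, 1]")
  add("survey_points", which(!p$stratum %in% c("urban", "rural")),
      "stratum", "not urban/rural")
  add("survey_points",
      which(!p$country_id %in% inputs$covariates$country_id),
      "country_id", "not in covariate table")
  cv <- inputs$covariates
  add("covariates", which(!cv$who_region %in% WHO_REGIONS), "who_region",
      "unknown WHO region")
  add("covariates", which(!cv$income_group %in% INCOME_GROUPS),
      "income_group", "unknown income group")
  add("covariates", which(cv$pop_urban < 0 | cv$pop_rural < 0),
      "pop_urban/pop_rural", "negative population")
  add("covariates", which(duplicated(cv$country_id)), "country_id",
      "duplicated country")
  r <- inputs$records
  add("observations", which(!r$hwws %in% c(0, 1)), "hwws", "not binary")
  add("observations",
      which(!is.na(r$facility_present) & !r$facility_present %in% c(0, 1)),
      "facility_present", "not binary")
  multi <- r |>
    dplyr::distinct(.data$household_id, .data$study_id) |>
    dplyr::count(.data$household_id) |>
    dplyr::filter(.data$n > 1)
  add("observations", which(r$household_id %in% multi$household_id),
      "household_id", "household appears in more than one study")
  m <- inputs$meta
  add("meta_studies",
      which(m$n_events < 1 | m$n_hwws < 0 | m$n_hwws > m$n_events),
      "n_events/n_hwws", "counts violate 0 <= n_hwws <= n_events >= 1")
  if (length(v)) dplyr::bind_rows(v) else {
    tibble::tibble(table = character(), row = integer(),
                   column = character(), problem = character())
  }
}

# population-weighted mean with delta-method SE for one stratum table
stratum_aggregate <- function(est, weights) {
  w <- weights / sum(weights)
  se <- se_from_ci(est$ci_low, est$ci_high)
  mu <- sum(w * est$estimate)
  s <- sqrt(sum(w^2 * se^2))
  tibble::tibble(estimate = mu,
                 ci_low = truncate01(mu - qnorm(0.975) * s),
                 ci_high = truncate01(mu + qnorm(0.975) * s))
}

#' Run the full estimation pipeline
#'
#' Executes the three objectives end to end: facility-presence modelling
#' with per-country CIs and population-weighted aggregation; the
#' conditional-prevalence model and high-income meta-analysis; and the
#' combination into country, regional and global HWWS estimates, with the
#' configured sensitivity analyses. Optionally writes publication-shaped
#' delimited tables and a reproducibility manifest.
#'
#' @param config an [hwws_config()].
#' @return a `hwws_run` list: `facility` (per-country and aggregated
#'   facility presence), `conditional` (model fit, prevalence ratio,
#'   regional table, descriptives), `meta` (pooled result, subgroups,
#'   leave-one-out influence), `hwws` (country estimates and aggregated
#'   tables), `sensitivity`, `validation`, `loo` and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "hwws_config"))
  inputs <- resolve_inputs(config)
  validation <- validate_inputs(inputs)

  if (config$target_year < min(inputs$points$year) - 10 ||
      config$target_year > max(inputs$points$year) + 10) {
    abort("`target_year` is far outside the survey data range.")
  }

  points <- inputs$points
  n_filtered <- 0L
  if (config$filter_post2009) {
    points <- filter_since(points, 2009)
    n_filtered <- attr(points, "n_removed")
  }

  fac <- estimate_facilities(points, inputs$covariates,
                             target_year = config$target_year,
                             n_draws = config$n_mc_draws,
                             seed = config$seed)
  fac_tables <- list(
    region_income = aggregate_estimates(fac$by_country, inputs$covariates,
                                        "region_income"),
    income = aggregate_estimates(fac$by_country, inputs$covariates,
                                 "income"),
    world = aggregate_estimates(fac$by_country, inputs$covariates,
                                "world"),
    urban = stratum_aggregate(
      dplyr::semi_join(fac$by_stratum$urban, inputs$covariates,
                       by = "country_id"),
      inputs$covariates$pop_urban),
    rural = stratum_aggregate(
      dplyr::semi_join(fac$by_stratum$rural, inputs$covariates,
                       by = "country_id"),
      inputs$covariates$pop_rural)
  )

  cond_fit <- fit_conditional_model(inputs$records)
  cond_table <- regional_prevalence_table(cond_fit)
  pr <- prevalence_ratio(cond_fit)
  descriptives <- describe_pooled_data(inputs$records)

  meta_res <- pool_random_effects(inputs$meta)
  meta_subgroup <- if ("who_region" %in% names(inputs$meta)) {
    subgroup_meta(inputs$meta, "who_region")
  } else {
    NULL
  }
  meta_loo <- leave_one_out_influence(inputs$meta)

  country_hwws <- country_hwws_estimates(
    fac$by_country, cond_table, meta_res,
    covariates = inputs$covariates, year = config$target_year)
  populations <- inputs$covariates |>
    dplyr::transmute(country_id = .data$country_id,
                     population = .data$pop_urban + .data$pop_rural)
  hwws_tables <- list(
    region_income = aggregate_hwws(country_hwws, populations,
                                   "region_income"),
    income = aggregate_hwws(country_hwws, populations, "income"),
    world = aggregate_hwws(country_hwws, populations, "world")
  )

  sensitivity <- NULL
  if (config$hic_eq1_sensitivity) {
    hic_fac <- fac_tables$income$estimate[fac_tables$income$group == "HIC"]
    lmi_without <- cond_table$prevalence[cond_table$facility == 0]
    if (length(hic_fac) == 1) {
      sensitivity <- tibble::tibble(
        scope = "HIC",
        method = "eq1-sensitivity",
        prevalence = sensitivity_hic_eq1(hic_fac, meta_res$pooled,
                                         lmi_without))
    }
  }

  loo <- NULL
  if (config$run_loo) {
    loo <- purrr::map(c(urban = "urban", rural = "rural"), function(s) {
      tryCatch(loo_cv_rmse(points, inputs$covariates,
                           target_year = config$target_year, stratum = s),
               error = function(e) NULL)
    })
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("handwashr")),
    seed = config$seed,
    target_year = config$target_year,
    n_mc_draws = config$n_mc_draws,
    filter_post2009 = config$filter_post2009,
    n_survey_points = nrow(points),
    n_points_prefilter_removed = n_filtered,
    n_countries = nrow(inputs$covariates),
    n_extrapolated = sum(fac$by_country$basis == "extrapolated"),
    n_observation_events = nrow(inputs$records),
    n_listwise_deleted = cond_fit$n_deleted,
    conditional_method = cond_fit$method,
    n_meta_studies = nrow(inputs$meta),
    n_validation_issues = nrow(validation)
  )

  out <- structure(
    list(facility = c(list(by_country = fac$by_country,
                           by_stratum = fac$by_stratum), fac_tables),
         conditional = list(fit = cond_fit, prevalence_ratio = pr,
                            regional_table = cond_table,
                            descriptives = descriptives),
         meta = list(pooled = meta_res, subgroup = meta_subgroup,
                     influence = meta_loo),
         hwws = c(list(by_country = country_hwws), hwws_tables),
         sensitivity = sensitivity,
         validation = validation,
         loo = loo,
         manifest = manifest),
    class = "hwws_run")
  if (!is.null(config$output_dir)) write_run_tables(out, config$output_dir)
  out
}

#' @export
print.hwws_run <- function(x, ...) {
  w <- x$hwws$world
  cat("HWWS estimation run (", x$manifest$target_year, ")\n", sep = "")
  cat(sprintf("  world HWWS after potential faecal contact: %.1f%% (%.1f, %.1f)\n",
              100 * w$prevalence, 100 * w$ci_low, 100 * w$ci_high))
  cat("  countries:", x$manifest$n_countries,
      "| extrapolated:", x$manifest$n_extrapolated,
      "| validation issues:", x$manifest$n_validation_issues, "\n")
  invisible(x)
}

#' Write the report tables of a pipeline run
#'
#' Emits delimited-text tables shaped like the publication tables (facility
#' presence by area, conditional prevalences by region, HWWS by area, the
#' per-country file with basis and method flags) plus a JSON manifest.
#'
#' @param run a `hwws_run` object.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_run_tables <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(
    facility_by_area = "facility_presence_by_area.tsv",
    conditional = "conditional_prevalence_by_region.tsv",
    hwws_by_area = "hwws_by_area.tsv",
    by_country = "hwws_by_country.tsv"
  )
  fac_area <- dplyr::bind_rows(
    run$facility$region_income,
    run$facility$income,
    run$facility$world,
    dplyr::mutate(run$facility$urban, group = "Urban"),
    dplyr::mutate(run$facility$rural, group = "Rural"))
  readr::write_tsv(fac_area, file.path(dir, files["facility_by_area"]))
  readr::write_tsv(run$conditional$regional_table,
                   file.path(dir, files["conditional"]))
  hwws_area <- dplyr::bind_rows(run$hwws$region_income, run$hwws$income,
                                run$hwws$world)
  readr::write_tsv(hwws_area, file.path(dir, files["hwws_by_area"]))
  per_country <- run$hwws$by_country |>
    dplyr::left_join(dplyr::select(run$facility$by_country, "country_id",
                                   facility_estimate = "estimate",
                                   facility_basis = "basis"),
                     by = "country_id")
  readr::write_tsv(per_country, file.path(dir, files["by_country"]))
  manifest_path <- file.path(dir, "manifest.json")
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(run$manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE)
  } else {
    writeLines(paste(names(run$manifest),
                     vapply(run$manifest, as.character, ""), sep = "\t"),
               manifest_path)
  }
  invisible(c(file.path(dir, files), manifest_path))
}
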