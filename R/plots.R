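#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Forest plot of a meta-analysis
#'
#' Study proportions with binomial CIs, point size proportional to the
#' random-effects weight, and the pooled estimate with its CI.
#'
#' @param object a `meta_result`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot meta_result
#' @export
autoplot.meta_result <- function(object, ...) {
  st <- object$studies |>
    dplyr::mutate(
      se = sqrt(.data$vi),
      lo = truncate01(.data$p - qnorm(0.975) * .data$se),
      hi = truncate01(.data$p + qnorm(0.975) * .data$se),
      study_id = factor(.data$study_id, levels = rev(.data$study_id)))
  ggplot2::ggplot(st, ggplot2::aes(x = .data$p, y = .data$study_id)) +
    ggplot2::geom_vline(xintercept = object$pooled, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::annotate("rect", xmin = object$ci_low, xmax = object$ci_high,
                      ymin = -Inf, ymax = Inf, alpha = 0.12,
                      fill = "steelblue") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                            height = 0.2) +
    ggplot2::geom_point(ggplot2::aes(size = .data$weight),
                        shape = 15, colour = "steelblue") +
    ggplot2::scale_size_area(max_size = 4, guide = "none") +
    ggplot2::labs(
      x = "Proportion of events followed by HWWS",
      y = NULL,
      title = sprintf(
        "Pooled %.2f (%.2f, %.2f); I² = %.1f%%",
        object$pooled, object$ci_low, object$ci_high, object$I2)) +
    ggplot2::theme_minimal()
}

#' Plot regional HWWS prevalence by facility presence
#'
#' Dot-and-interval display of the conditional-prevalence table, coloured
#' by facility presence and annotated with the provenance of each region's
#' prediction.
#'
#' @param table output of [regional_prevalence_table()].
#' @return a ggplot object.
#' @export
plot_regional_prevalence <- function(table) {
  dat <- dplyr::mutate(table,
                       facility = factor(.data$facility, c(0, 1),
                                         c("No facility", "Facility")))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$who_region,
                                    y = .data$prevalence,
                                    colour = .data$facility)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
      position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::geom_text(ggplot2::aes(label = substr(.data$provenance, 1, 1),
                                    y = .data$ci_high),
                       vjust = -0.6, size = 3, show.legend = FALSE) +
    ggplot2::labs(x = "WHO region",
                  y = "HWWS prevalence after potential faecal contact",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot country facility-presence estimates
#'
#' Sorted per-country estimates with CIs, coloured by whether the estimate
#' rests on the country's own survey data or is extrapolated from its
#' region and income group.
#'
#' @param estimates per-country estimate tibble (from [combine_strata()] or
#'   [estimate_facilities()]).
#' @return a ggplot object.
#' @export
plot_facility_estimates <- function(estimates) {
  dat <- dplyr::arrange(estimates, .data$estimate) |>
    dplyr::mutate(rank = dplyr::row_number())
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$rank, y = .data$estimate,
                                    colour = .data$basis)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low,
                                      ymax = .data$ci_high, group = 1),
                         fill = "grey85", colour = NA, alpha = 0.6) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "Countries (sorted)",
                  y = "Proportion with a designated handwashing facility",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
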