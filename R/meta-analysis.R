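#' DerSimonian-Laird random-effects pooling of study proportions
#'
#' Pools observed HWWS proportions across studies with the classical
#' DerSimonian-Laird estimator. By default pooling is on the raw proportion
#' scale with binomial variances `p(1-p)/n` (a symmetric pooled CI); the
#' logit scale is available as an option. Variances use Anscombe-stabilized
#' proportions (`+0.5` to successes and failures) so studies with observed
#' 0 or 1 keep a finite weight; the point estimates themselves are not
#' stabilized.
#'
#' The heterogeneity statistic `Q` is the fixed-effect weighted sum of
#' squares, `tau^2 = max(0, (Q - df) / (sum(w) - sum(w^2)/sum(w)))`, and
#' random-effects weights are `1 / (v_i + tau^2)`.
#'
#' @param studies tibble: `study_id`, `n_events`, `n_hwws` (plus free
#'   columns such as `who_region`, `setting`).
#' @param scale `"proportion"` (default) or `"logit"`.
#' @return a `meta_result` object: pooled proportion with CI, `tau2`, `Q`,
#'   `df`, `I2`, and a per-study tibble with normalized weights.
#' @export
pool_random_effects <- function(studies, scale = c("proportion", "logit")) {
  scale <- match.arg(scale)
  stopifnot(is.data.frame(studies),
            all(c("study_id", "n_events", "n_hwws") %in% names(studies)))
  if (nrow(studies) < 2) abort("Need at least 2 studies to pool.")
  if (any(studies$n_events < 1) ||
      any(studies$n_hwws < 0 | studies$n_hwws > studies$n_events)) {
    abort("Counts must satisfy 0 <= n_hwws <= n_events, n_events >= 1.")
  }
  p <- studies$n_hwws / studies$n_events
  p_stab <- (studies$n_hwws + 0.5) / (studies$n_events + 1)
  if (any(p %in% c(0, 1))) {
    inform("Boundary study proportion(s); stabilized variance applied.")
  }
  if (scale == "proportion") {
    yi <- p
    vi <- p_stab * (1 - p_stab) / studies$n_events
  } else {
    yi <- qlogis(p_stab)
    vi <- 1 / (studies$n_events * p_stab * (1 - p_stab))
  }
  w <- 1 / vi
  y_fe <- sum(w * yi) / sum(w)
  Q <- sum(w * (yi - y_fe)^2)
  df <- length(yi) - 1
  tau2 <- max(0, (Q - df) / (sum(w) - sum(w^2) / sum(w)))
  w_re <- 1 / (vi + tau2)
  pooled_y <- sum(w_re * yi) / sum(w_re)
  se <- sqrt(1 / sum(w_re))
  if (scale == "proportion") {
    pooled <- truncate01(pooled_y)
    ci <- truncate01(pooled_y + c(-1, 1) * qnorm(0.975) * se)
  } else {
    pooled <- plogis(pooled_y)
    ci <- plogis(pooled_y + c(-1, 1) * qnorm(0.975) * se)
  }
  structure(
    list(pooled = pooled, ci_low = ci[1], ci_high = ci[2],
         se = se, tau2 = tau2, Q = Q, df = df,
         I2 = i_squared(Q, df), scale = scale,
         studies = dplyr::mutate(studies, p = p, yi = yi, vi = vi,
                                 weight = w_re / sum(w_re))),
    class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat("Random-effects meta-analysis (DerSimonian-Laird,", x$scale,
      "scale)\n")
  cat(sprintf("  pooled proportion %.3f (95%% CI %.3f, %.3f) over %d studies\n",
              x$pooled, x$ci_low, x$ci_high, nrow(x$studies)))
  cat(sprintf("  Q = %.1f on %d df | tau^2 = %.4g | I^2 = %.1f%%\n",
              x$Q, x$df, x$tau2, x$I2))
  invisible(x)
}

#' Higgins' I-squared heterogeneity percentage
#'
#' `I^2 = 100 * max(0, (Q - df) / Q)`: the percentage of total variability
#' across studies attributable to between-study heterogeneity rather than
#' sampling error.
#'
#' @param Q heterogeneity (fixed-effect weighted sum of squares) statistic.
#' @param df its degrees of freedom (number of studies minus one).
#' @return percentage in `[0, 100]`.
#' @export
i_squared <- function(Q, df) {
  if (df < 1) abort("`df` must be at least 1.")
  if (Q <= 0) return(0)
  100 * max(0, (Q - df) / Q)
}

#' Subgroup random-effects meta-analysis
#'
#' Pools each subgroup independently; groups with fewer than 2 studies are
#' reported unpooled (their single study carried through with its own
#' binomial CI).
#'
#' @param studies study tibble as in [pool_random_effects()].
#' @param by name of the grouping column (string).
#' @param scale passed to [pool_random_effects()].
#' @return tibble: `group`, `n_studies`, `pooled`, `ci_low`, `ci_high`,
#'   `tau2`, `I2`, `pooled_flag`.
#' @export
subgroup_meta <- function(studies, by, scale = "proportion") {
  stopifnot(by %in% names(studies))
  studies |>
    dplyr::group_by(group = .data[[by]]) |>
    dplyr::group_map(function(d, key) {
      if (nrow(d) >= 2) {
        m <- pool_random_effects(d, scale = scale)
        tibble::tibble(group = key$group, n_studies = nrow(d),
                       pooled = m$pooled, ci_low = m$ci_low,
                       ci_high = m$ci_high, tau2 = m$tau2, I2 = m$I2,
                       pooled_flag = "pooled")
      } else {
        p <- d$n_hwws / d$n_events
        se <- sqrt(p * (1 - p) / d$n_events)
        tibble::tibble(group = key$group, n_studies = 1L, pooled = p,
                       ci_low = truncate01(p - qnorm(0.975) * se),
                       ci_high = truncate01(p + qnorm(0.975) * se),
                       tau2 = NA_real_, I2 = NA_real_,
                       pooled_flag = "unpooled")
      }
    }) |>
    dplyr::bind_rows()
}

#' Leave-one-out influence and outlier screening
#'
#' Recomputes the pooled estimate with each study omitted. A study is
#' flagged when its omission shifts the pooled estimate by more than
#' `shift_threshold` (proportion units, default 1.5 percentage points) or
#' when its externally standardized residual (against the leave-one-out
#' pooled estimate and heterogeneity) exceeds `resid_threshold`.
#'
#' @param studies study tibble as in [pool_random_effects()].
#' @param shift_threshold flag threshold on `|pooled - pooled_without|`.
#' @param resid_threshold flag threshold on the externally standardized
#'   residual.
#' @param scale passed to [pool_random_effects()].
#' @return tibble with one row per study: `study_id`, `pooled_without`,
#'   `shift`, `std_resid`, `flagged`.
#' @export
leave_one_out_influence <- function(studies, shift_threshold = 0.015,
                                    resid_threshold = 3,
                                    scale = "proportion") {
  if (nrow(studies) < 3) {
    abort("Need at least 3 studies for leave-one-out influence.")
  }
  full <- pool_random_effects(studies, scale = scale)
  purrr::map(seq_len(nrow(studies)), function(i) {
    loo <- pool_random_effects(studies[-i, ], scale = scale)
    yi <- full$studies$yi[i]
    vi <- full$studies$vi[i]
    loo_y <- if (scale == "logit") qlogis(loo$pooled) else loo$pooled
    z <- (yi - loo_y) / sqrt(vi + loo$tau2 + loo$se^2)
    tibble::tibble(study_id = studies$study_id[i],
                   pooled_without = loo$pooled,
                   shift = full$pooled - loo$pooled,
                   std_resid = z)
  }) |>
    dplyr::bind_rows() |>
    dplyr::mutate(flagged = abs(.data$shift) > shift_threshold |
                    abs(.data$std_resid) > resid_threshold)
}
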