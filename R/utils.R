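#' Clamp proportions away from the logit boundary
#'
#' Survey proportions of exactly 0 or 1 occur at small sample sizes and have
#' no finite logit. Before transforming, proportions are clamped to
#' `[lower, 1 - lower]` (default `[0.005, 0.995]`).
#'
#' @param p numeric vector of proportions in `[0, 1]`.
#' @param lower clamp bound; values below `lower` or above `1 - lower` are
#'   moved to the bound.
#' @return clamped numeric vector, with an attribute `n_clamped` giving the
#'   number of values moved.
#' @keywords internal
clamp_proportion <- function(p, lower = 0.005) {
  stopifnot(lower > 0, lower < 0.5)
  out <- pmin(pmax(p, lower), 1 - lower)
  attr(out, "n_clamped") <- sum(out != p, na.rm = TRUE)
  out
}

# run code with a locally-seeded RNG, restoring the caller's stream
with_local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# logit with clamped input (finite everywhere on [0,1])
safe_logit <- function(p, lower = 0.005) qlogis(clamp_proportion(p, lower))

assert_prob <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0 | x > 1)) {
    abort(sprintf("`%s` must be numeric in [0, 1].", name))
  }
  invisible(x)
}

# standard error recovered from a normal-approximation 95% CI
se_from_ci <- function(ci_low, ci_high) (ci_high - ci_low) / (2 * qnorm(0.975))

# truncate interval bounds to the proportion scale
truncate01 <- function(x) pmin(pmax(x, 0), 1)
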