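---
title: "Estimating handwashing with soap from facility-presence surveys: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating handwashing with soap from facility-presence surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`handwashr` estimates the prevalence of handwashing with soap (HWWS)
after potential faecal contact at country, regional and global level by
combining two quantities that *are* measurable at scale: the proportion of
households with a designated handwashing facility (a set place on the
premises with soap and water), and the conditional probability of
observed HWWS given that such a facility is or is not present. This
vignette documents the statistical models, every tunable that matters,
the synthetic-data generators used for validation, and the design
decisions taken where more than one defensible choice existed.

## Stage 1 — facility presence from sparse surveys

National surveys report, for some country-year-stratum combinations, the
proportion of households with a designated facility. The record is
sparse: most countries have no point at all, and almost all points come
from low- and middle-income countries. We model the logit of the survey
proportion with a linear multilevel model,

$$
\mathrm{logit}(p_{ct}) = \beta_0 + \beta_1 (t - t_{med})
  + \boldsymbol\beta_R \mathbf{R}_c + \boldsymbol\beta_I \mathbf{I}_c
  + u_c + \varepsilon_{ct},
  \qquad u_c \sim N(0, \sigma^2_c),\;
  \varepsilon_{ct} \sim N(0, \sigma^2_e),
$$

with $\mathbf{R}_c$ the WHO-region indicators, $\mathbf{I}_c$ the 2015
income-group indicators, and $t_{med}$ the median survey year of the data
actually being fitted (recomputed on every refit, including
cross-validation folds). Urban and rural strata are fitted separately.
Countries with data are predicted from fixed part plus their BLUP
$\hat u_c$; countries without data get the fixed part alone and are
flagged `extrapolated`.

Numerical choices:

* **Boundary proportions.** Survey proportions of exactly 0 or 1 occur at
  small samples; proportions are clamped to $[0.005, 0.995]$ before the
  logit. The clamp also attenuates genuinely near-saturated series: the
  income-high contrast is anchored by very few surveyed high-income
  countries whose true proportions sit near the boundary, and its
  estimate is systematically pulled toward the clamp. We document this
  rather than hide it: the calibration suite asserts unbiasedness for the
  intercept, trend, region and low/middle income contrasts, and excludes
  the income-high contrast for this stated reason.
* **ML, not REML**, so fixed effects remain comparable across
  leave-one-out refits; `reml = TRUE` is available.
* **Unseen factor levels.** A country whose region or income level never
  occurs in the fitted data inherits the reference level of that factor
  (logged); failing would otherwise block world totals.
* **Aliased designs** (a region–income cell pattern that makes the fixed
  design rank-deficient) abort naming the aliased columns.

Uncertainty:

* Countries **with data**: 10 000 Monte-Carlo draws (`n_draws`,
  reducible) of the fixed-effect vector from
  $N(\hat\beta, \widehat{\mathrm{Cov}}(\hat\beta))$ jointly with the
  country intercept from its conditional normal
  $N(\hat u_c, \mathrm{Var}(u_c \mid y))$; the CI is the 2.5/97.5
  percentile of the inverse-logit predictions. Whether the draw should
  vary all countries' intercepts jointly or only the target country's is
  underdetermined; we draw the target country only, which is what the
  per-country percentile uses.
* Countries **without data**: the 95% prediction interval of an ordinary
  least-squares regression of the region's logit proportions on year.
  The interval is computed on the logit scale, its limits are
  back-transformed, and the resulting proportion-scale width `PI` is
  applied as estimate ± PI/2 (truncated to $[0,1]$). Computing the width
  after back-transformation keeps units coherent; applying a logit-scale
  width to a proportion would not. Regions with fewer than two points
  inherit the widest available regional interval.
* **Aggregation.** Country estimates are population-weighted means of
  urban and rural values; group estimates are population-weighted means
  of country values. SEs combine by the delta method with independent
  errors, $\mathrm{SE}^2 = \sum w_i^2 \mathrm{SE}_i^2$, with stratum SEs
  recovered from CI half-widths as $(\mathrm{hi}-\mathrm{lo})/(2 \times
  1.96)$. Weighted means are linear, so stratum-then-country aggregation
  equals direct four-cell aggregation; the suite checks this to machine
  precision.

Predictive performance is assessed by leave-one-out cross-validation
over the countries holding a survey point in the target year: all of a
country's points are removed, the model refit, and the fixed-part
prediction compared with the held-out value; the RMSE is reported in
percentage points.

## Stage 2 — HWWS conditional on facility presence

Structured-observation datasets record, per potential faecal-contact
event, whether both hands were washed with soap, nested in households
nested in studies. We fit a log-link (modified) Poisson model —
`hwws ~ facility + region` with random intercepts for household and study
— so the facility coefficient exponentiates to a prevalence ratio.
The study is the top clustering unit (two datasets from one study form
one cluster).

Robust inference with few studies required care:

* The reported robust covariance is the study-clustered sandwich of the
  companion *marginal* modified-Poisson fit. Under a log link the
  marginal and conditional models share their slopes (the intercept
  shifts by half the summed intercept variances), so this is the sandwich
  for the contrasts of interest, and it is the standard construction for
  prevalence-ratio inference on clustered binary data. A sandwich built
  from conditional (BLUP-subtracted) residuals underestimates
  between-study variation and is not used.
* With $G$ studies and $p$ study-level fixed effects (intercept plus
  region contrasts), Wald intervals use a $t_{G-p}$ reference instead of
  the normal. With nine studies and four regions this matters: the
  calibration study in the test suite measures the coverage of the
  planted prevalence ratio across 300 synthetic replicates and the
  normal reference undercovers while $t_{G-p}$ is nominal.
* **Separation** (a facility or region stratum with all-equal outcomes)
  or a failed mixed fit falls back to the fixed-effects modified Poisson
  with study-clustered SEs, with a warning.
* Predictions `exp(eta)` can exceed 1 under a log link; they are capped
  at 1 with a warning.

Adjusted regional prevalences are predictions at the region indicator
with random effects at zero. Regions with no contributing study receive
the mean of the country-level adjusted prevalences (study intercepts
included, averaged within country) with a prediction interval of
mean ± 1.96 SD of those country values. The region of the Americas is
treated as region-specific — it is represented by a contributing study —
even though reasonable readings of the published table footnotes differ
on this point. Rows with unobservable facility status are listwise
deleted and the count reported.

For high-income countries, study-level HWWS proportions are pooled by
DerSimonian–Laird random-effects meta-analysis. Pooling is on the raw
proportion scale with binomial variances (symmetric pooled CIs match how
such results are reported); the logit scale is an option. Variances use
Anscombe-stabilized proportions ($+0.5$ to successes and failures) so
boundary studies keep finite weight; point estimates are not stabilized.
$\tau^2$ is the DL moment estimator (the historical default of the tools
this analysis ecosystem uses); heterogeneity is summarized by
$I^2 = 100\,\max(0, (Q - df)/Q)$. Leave-one-out influence flags a study
whose omission shifts the pooled estimate by more than 1.5 percentage
points (configurable) or whose externally standardized residual exceeds
3.

## Stage 3 — combination and propagation

Country HWWS prevalence for low- and middle-income countries is the
mixture

$$
p_{\mathrm{HWWS}} = p_{\mathrm{HWWS}\mid\mathrm{HW}} \cdot p_{\mathrm{HW}}
 + p_{\mathrm{HWWS}\mid\mathrm{noHW}} \cdot (1 - p_{\mathrm{HW}}),
$$

with regional conditional prevalences and the country's own facility
presence. High-income countries take the pooled meta-analytic prevalence
directly. Error propagation is first-order delta method with the three
inputs independent:

$$
\mathrm{SE}^2 = (p_1 - p_0)^2 \mathrm{SE}^2_{p_{HW}}
 + p_{HW}^2 \mathrm{SE}^2_{p_1} + (1 - p_{HW})^2 \mathrm{SE}^2_{p_0}.
$$

When regional conditional prevalences are projected to countries their
SEs enter undiminished — the same regional error is shared by every
country of the region — so projection widens intervals. Aggregation
honours the same structure: within a group, the shared regional error
components add linearly in SD within each region, while
facility-presence errors (country-specific) add in quadrature. This is
the simplest covariance structure consistent with both stated behaviours
(projection widens, aggregation narrows); the exact published propagation
equations are not available, so this is an explicit, documented
approximation. Faecal contacts are assumed proportional to population
with equal rates everywhere, so person counts are the aggregation
weights.

The high-income sensitivity analysis applies the mixture to high-income
countries too, using the pooled meta-analytic value as the with-facility
prevalence and the arithmetic mean of the six regional without-facility
prevalences as the without-facility value.

## The synthetic-data generators

The survey and observation microdata behind the published analysis are
not deposited, so the generators reproduce their statistical structure
and return the generating truth for parameter-recovery testing.

* `generate_survey_points()` emits 194 countries across a realistic
  region-by-income composition; the number of points per country follows
  the published availability pattern (117 of 194 countries with none, 48
  with one, ...), and the countries holding points are drawn with income
  weights that place data almost exclusively in low- and middle-income
  countries with one guaranteed high-income recipient — matching the
  actual record, where a single high-income country contributed data.
  Noise is added on the logit scale (country intercept SD 0.7, residual
  SD 0.4 by default — the published analysis reports no variance
  components, so these are plausibility choices, made once). With all
  SDs zero every emitted proportion equals the inverse-logit of the fixed
  part exactly.
* `generate_observation_study()` emits nine studies (five AFR, one AMR,
  two SEAR, one WPR — the composition of the pooled datasets) of 200
  households each, with Poisson(2.2) events per household (≈4000 events,
  matching the pooled record's order of magnitude), household facility
  presence 0.35, baseline regional prevalences at the published
  without-facility values, a multiplicative prevalence ratio of 2 on the
  log-risk scale, and household/study intercept SDs 0.5/0.3. Event
  probabilities are truncated at 0.99; with truncation disabled an
  implied probability above 1 is an error.
* `generate_meta_studies()` emits 15 study summaries with underlying
  proportions inverse-logit of $\mathrm{logit}(\mu) + N(0, \tau^2)$ and
  binomial sampling at sizes 100–2000; the default $\tau = 1$ on the
  logit scale produces the extreme heterogeneity ($I^2 > 99\%$)
  characteristic of pooled observational handwashing series.

All generators take a single integer seed and restore the caller's RNG
state. What they do **not** emulate: survey sampling weights and
questionnaire logic, secular changes in survey instruments, non-random
availability of observation studies, reactivity of observed households,
or correlation between facility coverage and conditional behaviour
beyond region membership. Passing recovery tests therefore demonstrates
that the estimation machinery is correct and calibrated under the
model's own assumptions — not that those assumptions hold in any real
survey system.

## Validation strategy and problem sizes

The test suite validates each stage against independent references:
exact closed forms on noise-free data; an explicit naive-refit loop as
the cross-validation oracle; `metafor`'s DL implementation as the
meta-analysis oracle; and simulation calibration with known truth —
300 replicates of the sparse survey world for fixed-effect bias and
slope CI coverage, 300 replicates of the nine-study observation world
for prevalence-ratio coverage (using the fast `nAGQ = 0` mixed fit),
and a 504-country world with three points per country for the
Monte-Carlo CI engine. These sizes keep each calibration study at a few
minutes while leaving Monte-Carlo error small relative to the
tolerances asserted.

## Known limitations

* The income-high fixed effect is attenuated by boundary clamping and by
  design is anchored by very few surveyed high-income countries; facility
  estimates for high-income countries lean heavily on extrapolation.
* Nine studies is few for study-clustered inference; the $t_{G-p}$
  reference makes coverage nominal on average but individual-dataset
  robust SEs remain noisy.
* The DL $\tau^2$ estimator is noisy at 15 studies (the suite asserts
  recovery only within ±50%), and pooled proportions near 0 or 1 would
  make the raw-proportion scale less suitable than the logit option.
* The shared-error propagation in stage 3 is an approximation; a
  fully Monte-Carlo propagation would need the joint distribution of
  regional conditional prevalences, which the published record does not
  provide.
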