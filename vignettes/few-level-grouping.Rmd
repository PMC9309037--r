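---
title: "Fixed or random? Simulating grouping variables with few levels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fixed or random? Simulating grouping variables with few levels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(levelsim)
```

## The question and the model

Hierarchical data with a grouping variable of only 2–8 levels put an
analyst in an uncomfortable spot: a random effect's variance is then
estimated from very few draws, is biased towards zero, and frequently hits
the boundary of the parameter space (a *singular fit*). `levelsim`
quantifies what this does to the statistical properties of the
*population-level* effect — the average slope (and intercept) across
levels — by simulation.

The data-generating process is a plant-height study on `m` mountains:

$$H_{ij} = (\beta_0 + b_{0i}) + (\beta_1 + b_{1i})\,T_{ij} + \varepsilon_{ij},
\qquad b_{0i} \sim N(0, \sigma^2_{b0}),\;
b_{1i} \sim N(0, \sigma^2_{b1}),\;
\varepsilon_{ij} \sim N(0, \sigma^2_e),$$

with intercept and slope deviations drawn independently. Scenario A fixes
$\sigma^2_{b1}=0$ (mountains differ only in mean height); scenario B lets
both vary. The tested models bracket these processes from below and above:
pooled regression that omits the grouping variable (`M2`/`M7`), fixed
mountain effects (`M3`) or fixed mountain-by-temperature interactions
(`M8`), a random intercept (`M4`/`M9`), independent random intercept and
slope (`M5`/`M10`), and a correlated pair (`M11`).

## The generator and its defaults

All parameters live in `scenario_config()`; the defaults are the study
conditions and are not meant to be tuned per run.

* **Effects**: $\beta_0 = \beta_1 = 0.4$ cm under the alternative
  ("weak effect"), $0$ under the null. Random-effect variances of
  $0.01$ or $0.25$ cm² represent a small and a large between-mountain
  spread.
* **Residual noise** `resid_sd` ($\sigma_e$, cm): defaults to 1.0. The
  generator's other magnitudes only acquire meaning relative to this
  scale; with $\bar n = 200$ plants per mountain the pooled-regression
  slope test then has the large-sample inflated type I error
  $2\Phi(-z_{0.975}/\sqrt{1 + \bar n\,\sigma^2_{b1}/\sigma^2_e})$,
  i.e. $\approx 0.26$ and $\approx 0.78$ at the two variance settings —
  the regime the framework is designed to exhibit. The value is exposed
  in the configuration for sensitivity analyses; small-`m` power and the
  singularity-stratified rates are the quantities most sensitive to it.
* **Unbalance**: each mountain's share of the total is drawn uniformly on
  $[0.1, 0.9]$, normalized, converted to integer counts by
  largest-remainder rounding, and redrawn until every count lies in
  `count_range` (default 40–360 at 200 plants per mountain on average).
  Note a consequence: unbalanced shares raise the *effective* plants per
  mountain, $n\sum_i s_i^2 > n/m$, so pooled-model inflation sits
  slightly above the balanced-design formula.
* **Temperature**: i.i.d. standard normal per plant, z-scored within the
  dataset — "standardized temperature" with no spatial structure.
* **Seeds**: one RNG stream per dataset (`withr::with_seed`); in
  replicated grids, replicate $r$ of every condition uses
  `master_seed + r` for everything it does (simulation, fitting,
  bootstrap), which makes results independent of execution order and
  induces common random numbers across conditions.

What the generator does *not* emulate: spatial or transect
autocorrelation, non-Gaussian responses, measurement error in
temperature, or correlated intercept–slope deviations (the generator is
scenario B; only the *tested* model `M11` estimates a correlation).
Passing tests therefore speak to the behaviour of estimators under a
clean hierarchical Gaussian world, not to robustness against these
features of real data.

## The mixed-model engine

`fit_lmm()` implements profiled (restricted) maximum likelihood directly.
The per-mountain random-effect covariance is parameterized by its
*relative Cholesky factor* $\Lambda(\theta)$ — the Cholesky factor of the
covariance divided by $\sigma^2_e$ — so the marginal covariance of one
mountain's data is $\sigma_e^2 (I + Z_i\Lambda\Lambda'Z_i')$ and the
boundary "variance exactly zero / correlation exactly $\pm 1$" is simply a
zero diagonal entry of $\Lambda$. Uncorrelated structures constrain the
off-diagonal to zero.

Because both the fixed effects and $\sigma^2_e$ profile out in closed
form, the criterion reduces to per-mountain $2\times 2$ algebra on
sufficient statistics ($n_i, \sum T, \sum T^2, \sum H, \sum TH, \sum H^2$)
via the Woodbury identity. An evaluation costs O(m) independent of the
number of plants, which is what makes $10^4$-replicate grids affordable in
minutes.

Numerical choices:

* **Optimizer**: the single-parameter (random-intercept) profile is
  unimodal in $|\theta|$, so golden-section search on $[0, 25]$ plus an
  explicit evaluation at $\theta = 0$ is both faster and safer than
  quasi-Newton — the profiled criterion is an even function of a diagonal
  $\theta$, so finite-difference gradients vanish at the boundary and can
  strand a gradient method there. Two- and three-parameter structures
  evaluate five deterministic starts (a moment-based start from pooled-OLS
  residuals, $\times\tfrac14$, $\times 4$, and two fixed fallbacks) and
  run bounded `L-BFGS-B` from the best two; boundary optima are reached
  exactly. Criterion agreement with an independent dense-matrix
  implementation and with `lme4` is at the $10^{-8}$ level in the test
  suite.
* **Singularity**: `is_singular()` flags $\min(\mathrm{diag}\,\Lambda) <
  10^{-4}$, or a correlation within $10^{-4}$ of $\pm 1$ — the ecosystem
  convention for boundary fits.
* **Satterthwaite tests**: `satterthwaite_test()` computes
  $df = 2v^2/(g'Ag)$ with $v$ the coefficient variance, $g$ its gradient
  in the variance parameters $(\theta, \sigma)$ and $A$ twice the inverse
  finite-difference Hessian of the criterion (step
  $10^{-4}(1+|\eta_k|)$, central differences). When the Hessian is not
  positive definite — common at boundary fits, where the even symmetry
  can make curvature vanish — the test falls back to the residual
  $n - p$ degrees of freedom; df are floored at 1. Satterthwaite is the
  only df approximation implemented; Kenward–Roger is out of scope.
* **ML vs REML**: both are available; ML's uncorrected variance estimates
  produce more boundary estimates and stronger downward bias, which the
  metrics module exposes on shared datasets.

## Fixed-effects models and the population-level slope

`fit_ols()` delegates to `lm()`. For the per-mountain-slopes model `M8`
the population-level slope is a (weighted) average of $m$ slope
coefficients; `population_slope_bootstrap()` draws coefficient vectors
from $N(\hat\gamma, \widehat{\mathrm{Cov}}(\hat\gamma))$ — a parametric
bootstrap on the coefficient scale, not a case-resampling bootstrap —
averages the slopes per draw, and reports the bootstrap standard
deviation with a standard-normal reference for the p-value (the statistic
is a smooth linear functional, and the draw count defaults to $10^4$
where the Monte-Carlo error of the se is below 1%). Default weights are
equal ($1/m$): broad-sense inference treats mountains symmetrically;
`by_count` weights are available because unbalanced designs make the two
weightings genuinely different.

## Metrics and aggregation policies

`run_grid()` fits every requested model to the same simulated datasets
and aggregates slope-test rejection rates at $\alpha = 0.05$ (strict
inequality; ties have probability zero) under three policies —
non-singular fits only, all fits, and stratified singular vs non-singular
— because the three answer different questions: the analyst who trusts a
clean fit, the unconditional frequentist property, and the mechanism by
which boundary fits distort inference. Fixed-effects models have no
singularity flag and always use all datasets. Printed "average" rates
aggregate over the `m` range within one variance setting and policy;
per-`m` curves are always retained. `summarize_varcomp()` reports the
point mass at zero (boundary estimates), mean and median per term, for
all fits and the non-singular subset — truncating the zero mass biases
the mean upward, which is the cost of discarding singular fits.

## The design sweep and the quantile splines

`run_sweep()` samples study designs uniformly: $m \in \{2,\dots,20\}$, a
common random-effect variance in $[10^{-4}, 4]$, $10$–$500$ observations
per level, and per-level shares on $[0.1, 0.9]$ (at least 3 plants per
mountain; the difference between the largest and smallest share is the
unbalance proxy). Counts are fixed once per design point; each point
accumulates a target number of *non-singular* `M10` fits (the fixed-model
`M8` uses every simulated dataset), with a retry budget of 8 times the
target, after which the point is flagged and should be excluded —
tiny-variance designs can be singular almost surely.

The defaults are desk-scale — 200 design points × 200 fits, against
1000 × 1000 at full scale — chosen to preserve the shapes of the partial
effects at roughly 25× less compute; both knobs are arguments.

Rates are then summarised by an additive quantile regression: cubic
B-spline bases per covariate (10 basis functions by default,
covariates standardized internally), a second-order difference penalty,
and the pinball loss at $\tau = 0.5$ — the median response surface, with
$\tau$ configurable — minimized by iteratively reweighted least squares
on a smoothed absolute residual. The penalty weight is chosen by
five-fold cross-validated pinball loss over a log-spaced grid. This is a
re-specification of the additive-quantile idea in plain form rather than
a wrapper around an existing smoother; the test suite verifies median
recovery of a known nonlinear curve to 0.1 absolute error and
monotonicity of the training loss in the penalty. No uncertainty bands
are produced for the partial-effect curves, and no interaction smooths.

## Problem sizes used by the tests

The packaged acceptance checks run 1000 replicates per condition over
$m = 2..8$ (2000 for the stratified scenario-B grid, so both strata are
populated at large `m`), and a 60-point × 50-fit type-I-only sweep —
sizes chosen as a deliberate compromise so the whole suite completes in
about ten minutes on one CPU while keeping binomial Monte-Carlo error
near half a percentage point on a 5% rate. `scripts/acceptance.R`
re-runs the same experiments from a caller-supplied seed.

## Known limitations

* The singularity-*stratified* rates are the quantities most sensitive to
  the residual-noise scale and to exactly which model's boundary flag
  defines the strata; they should be interpreted relative to this
  package's conventions (flag from the fitted model itself, $\sigma_e=1$).
* Satterthwaite p-values on *singular* fits use a boundary Hessian or the
  residual-df fallback; they are reported because the stratified analysis
  needs them, but no claim of calibration is made there — that
  miscalibration is, in fact, the phenomenon under study.
* The engine covers exactly the model family of the study design (one
  grouping factor, intercept and one slope); it is not a general mixed-
  model replacement — that is what keeps it fast and exhaustively
  testable.
* Quantile-spline curves are point estimates; comparing families by eye
  should account for the Monte-Carlo noise of the per-point rates.
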