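#' Empirical rejection rate of a set of p-values
#'
#' Fraction of p-values strictly below the significance level, with its
#' binomial Monte-Carlo standard error \eqn{\sqrt{r(1-r)/n}}.
#'
#' @param p_values Vector of p-values in \[0, 1\].
#' @param alpha Significance level (default 0.05).
#'
#' @return One-row tibble: `rejection_rate`, `n_used`, `mc_se`.
#' @examples
#' rejection_rate(c(0.01, 0.5), alpha = 0.05)
#' @export
rejection_rate <- function(p_values, alpha = 0.05) {
  p_values <- p_values[!is.na(p_values)]
  if (!length(p_values)) {
    abort("`p_values` is empty; no rejection rate can be computed.")
  }
  if (any(p_values < 0 | p_values > 1)) {
    abort("p-values must lie in [0, 1].")
  }
  r <- mean(p_values < alpha)
  tibble::tibble(rejection_rate = r, n_used = length(p_values),
                 mc_se = sqrt(r * (1 - r) / length(p_values)))
}

default_models <- function(scenario) {
  if (scenario == "A") c("M2", "M3", "M4", "M5")
  else c("M7", "M8", "M9", "M10", "M11")
}

#' Configure a replicated simulation grid
#'
#' @param scenarios Character subset of `c("A", "B")`.
#' @param m_values Numbers of mountains to simulate (default 2..8).
#' @param variances Random-effect variances to simulate (default 0.01 and
#'   0.25; in scenario B intercept and slope variances are set equal).
#' @param effect `"null"` (all population-level effects 0; type I error) or
#'   `"weak"` (intercept and slope 0.4 cm; power).
#' @param n_reps Replicates per condition (>= 100 for meaningful rates; the
#'   desk default is 1000).
#' @param alpha Significance level.
#' @param singular_policy Aggregation policies for mixed-model fits:
#'   any subset of `"nonsingular_only"`, `"all"`, `"stratified"`.
#'   Fixed-effects models are always aggregated over all datasets.
#' @param models Model ids to fit, or `NULL` for every tested model of each
#'   scenario.
#' @param estimator `"REML"` or `"ML"` for the mixed models.
#' @param resid_sd Residual standard deviation of the generator (cm).
#' @param mean_plants_per_mountain Expected plants per mountain.
#' @param bootstrap_draws Bootstrap draws for the `M8` population slope.
#' @param coefficient Which population-level coefficient to test
#'   (`"temperature"` or `"(Intercept)"`).
#' @param master_seed Integer; replicate r uses seed `master_seed + r`.
#'
#' @return A `run_config` list.
#' @export
run_config <- function(scenarios = "A", m_values = 2:8,
                       variances = c(0.01, 0.25),
                       effect = c("null", "weak"),
                       n_reps = 1000, alpha = 0.05,
                       singular_policy = c("nonsingular_only", "all",
                                           "stratified"),
                       models = NULL, estimator = "REML", resid_sd = 1,
                       mean_plants_per_mountain = 200L,
                       bootstrap_draws = 1000,
                       coefficient = "temperature",
                       master_seed = 1L) {
  effect <- match.arg(effect)
  singular_policy <- match.arg(singular_policy, several.ok = TRUE)
  stopifnot(all(scenarios %in% c("A", "B")))
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie in (0, 1).")
  if (n_reps < 1) abort("`n_reps` must be positive.")
  structure(
    list(scenarios = scenarios, m_values = as.integer(m_values),
         variances = variances, effect = effect,
         n_reps = as.integer(n_reps), alpha = alpha,
         singular_policy = singular_policy, models = models,
         estimator = estimator, resid_sd = resid_sd,
         mean_plants_per_mountain = as.integer(mean_plants_per_mountain),
         bootstrap_draws = bootstrap_draws, coefficient = coefficient,
         master_seed = as.integer(master_seed)),
    class = "run_config")
}

#' Run the simulation grid
#'
#' For every condition (scenario x number of mountains x random-effect
#' variance) simulates `n_reps` datasets, fits the requested tested models,
#' records the population-level slope test of each, and aggregates empirical
#' rejection rates (type I error under `effect = "null"`, power under
#' `effect = "weak"`), singular-fit fractions and variance-component
#' estimates.  Replicate r of every condition uses seed
#' `master_seed + r` for its single RNG stream (dataset, fits, bootstrap),
#' so results are reproducible and independent of execution order.
#'
#' @param cfg A [run_config()].
#'
#' @return An object of class `level_grid`: a list with
#' * `metrics` — one row per condition x model x aggregation policy:
#'   `rejection_rate`, `n_used`, `mc_se`, `singular_fraction`;
#' * `results` — one row per replicate x model with the slope test;
#' * `varcomp` — per-replicate variance-component estimates (mixed models);
#' * `varcomp_summary` — [summarize_varcomp()] output per condition;
#' * `config` — the configuration.
#' @examples
#' \donttest{
#' g <- run_grid(run_config("A", m_values = c(2, 5), variances = 0.25,
#'                          models = "M4", n_reps = 100))
#' g$metrics
#' }
#' @export
run_grid <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  beta <- if (cfg$effect == "null") 0 else 0.4
  conditions <- tidyr::expand_grid(scenario = cfg$scenarios,
                                   m = cfg$m_values,
                                   variance = cfg$variances)
  res_rows <- list()
  vc_rows <- list()
  for (ci in seq_len(nrow(conditions))) {
    scen <- conditions$scenario[ci]
    m <- conditions$m[ci]
    v <- conditions$variance[ci]
    models <- if (is.null(cfg$models)) default_models(scen) else cfg$models
    mixed <- models %in% names(lmm_models)
    nm <- length(models)
    p_mat <- matrix(NA_real_, cfg$n_reps, nm)
    est_mat <- matrix(NA_real_, cfg$n_reps, nm)
    se_mat <- matrix(NA_real_, cfg$n_reps, nm)
    df_mat <- matrix(NA_real_, cfg$n_reps, nm)
    sing_mat <- matrix(NA, cfg$n_reps, nm)
    vc_int <- matrix(NA_real_, cfg$n_reps, nm)
    vc_slo <- matrix(NA_real_, cfg$n_reps, nm)
    for (r in seq_len(cfg$n_reps)) {
      seed_r <- cfg$master_seed + r
      withr::with_seed(seed_r, {
        sc <- scenario_config(
          scenario = scen, n_mountains = m,
          beta_intercept = beta, beta_slope = beta,
          var_intercept = v, var_slope = v, resid_sd = cfg$resid_sd,
          mean_plants_per_mountain = cfg$mean_plants_per_mountain)
        data <- simulate_dataset(sc)
        for (k in seq_len(nm)) {
          if (mixed[k]) {
            fit <- fit_lmm(data, models[k], estimator = cfg$estimator)
            tst <- satterthwaite_test(fit, cfg$coefficient)
            sing_mat[r, k] <- fit$singular
            vc_int[r, k] <- fit$varcomp$sigma2_intercept
            vc_slo[r, k] <- fit$varcomp$sigma2_slope
          } else {
            fit <- fit_ols(data, models[k])
            tst <- if (cfg$coefficient == "temperature") {
              ols_slope_test(fit, n_draws = cfg$bootstrap_draws)
            } else {
              td <- tidy(fit)
              td[match("(Intercept)", td$coefficient), ]
            }
          }
          p_mat[r, k] <- tst$p.value
          est_mat[r, k] <- tst$estimate
          se_mat[r, k] <- tst$se
          df_mat[r, k] <- tst$df
        }
      })
    }
    res_rows[[ci]] <- tibble::tibble(
      scenario = scen, m = m, variance = v, effect = cfg$effect,
      model = rep(models, each = cfg$n_reps),
      rep = rep(seq_len(cfg$n_reps), nm),
      seed = cfg$master_seed + rep(seq_len(cfg$n_reps), nm),
      estimate = as.vector(est_mat), se = as.vector(se_mat),
      df = as.vector(df_mat), p.value = as.vector(p_mat),
      singular = as.vector(sing_mat))
    if (any(mixed)) {
      vc_rows[[ci]] <- tibble::tibble(
        scenario = scen, m = m, variance = v, effect = cfg$effect,
        model = rep(models[mixed], each = cfg$n_reps),
        rep = rep(seq_len(cfg$n_reps), sum(mixed)),
        sigma2_intercept = as.vector(vc_int[, mixed, drop = FALSE]),
        sigma2_slope = as.vector(vc_slo[, mixed, drop = FALSE]),
        singular = as.vector(sing_mat[, mixed, drop = FALSE]))
    }
  }
  results <- dplyr::bind_rows(res_rows)
  varcomp <- dplyr::bind_rows(vc_rows)
  out <- list(metrics = aggregate_metrics(results, cfg$alpha,
                                          cfg$singular_policy),
              results = results, varcomp = varcomp,
              varcomp_summary = if (nrow(varcomp))
                summarize_varcomp_grid(varcomp) else NULL,
              config = cfg)
  class(out) <- "level_grid"
  out
}

#' @export
print.level_grid <- function(x, ...) {
  cat(sprintf("<level_grid> %s effect, %d replicates per condition\n",
              x$config$effect, x$config$n_reps))
  print(x$metrics, n = 20)
  invisible(x)
}

# One metrics row per condition x model x policy.
aggregate_metrics <- function(results, alpha, policies) {
  grp <- c("scenario", "m", "variance", "effect", "model")
  one <- function(df, keep, policy) {
    p <- df$p.value[keep]
    n_used <- sum(!is.na(p))
    r <- if (n_used) mean(p < alpha, na.rm = TRUE) else NA_real_
    tibble::tibble(
      singular_policy = policy, rejection_rate = r, n_used = n_used,
      mc_se = if (n_used) sqrt(r * (1 - r) / n_used) else NA_real_,
      singular_fraction = mean(df$singular))
  }
  results |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::group_modify(function(df, key) {
      is_mixed <- key$model %in% names(lmm_models)
      if (!is_mixed) return(one(df, rep(TRUE, nrow(df)), "all"))
      dplyr::bind_rows(lapply(policies, function(pol) {
        switch(pol,
          nonsingular_only = one(df, !df$singular, "nonsingular_only"),
          all = one(df, rep(TRUE, nrow(df)), "all"),
          stratified = dplyr::bind_rows(
            one(df, df$singular, "singular_stratum"),
            one(df, !df$singular, "nonsingular_stratum")))
      }))
    }) |>
    dplyr::ungroup()
}

#' Summarize variance-component estimate distributions
#'
#' For a collection of mixed-model fits sharing one specification, reports
#' the zero mass (fraction of boundary estimates), mean and median of the
#' variance estimates for each random-effect term, computed over all fits
#' and over the non-singular subset.  The null distribution of a variance
#' estimate is a point mass at zero mixed with a right-skewed continuous
#' part, so dropping singular fits biases the mean upwards.
#'
#' @param fits A list of [fit_lmm()] objects, or a data frame with columns
#'   `sigma2_intercept`, `sigma2_slope`, `singular` (as in
#'   `run_grid()$varcomp`).
#' @param true_values Named numeric: generating variances, e.g.
#'   `c(sigma2_intercept = 0.01, sigma2_slope = 0.01)`.
#' @param zero_tol Estimates below this value count as the boundary mass.
#'
#' @return A tibble with one row per term x subset (`all`, `nonsingular`):
#'   `zero_mass`, `mean`, `median`, `true_value`, `n`.
#' @export
summarize_varcomp <- function(fits, true_values = NULL, zero_tol = 1e-8) {
  df <- if (is.data.frame(fits)) fits else {
    stopifnot(all(vapply(fits, inherits, logical(1), "lmm_fit")))
    tibble::tibble(
      sigma2_intercept = vapply(fits, function(f)
        f$varcomp$sigma2_intercept, numeric(1)),
      sigma2_slope = vapply(fits, function(f)
        f$varcomp$sigma2_slope, numeric(1)),
      singular = vapply(fits, function(f) f$singular, logical(1)))
  }
  terms <- intersect(c("sigma2_intercept", "sigma2_slope"), names(df))
  out <- list()
  for (term in terms) {
    x <- df[[term]]
    for (subset in c("all", "nonsingular")) {
      xs <- if (subset == "all") x else x[!df$singular]
      out[[length(out) + 1L]] <- tibble::tibble(
        term = term, subset = subset,
        zero_mass = mean(xs < zero_tol),
        mean = mean(xs), median = median(xs),
        true_value = if (!is.null(true_values) && term %in% names(true_values))
          unname(true_values[term]) else NA_real_,
        n = length(xs))
    }
  }
  dplyr::bind_rows(out)
}

summarize_varcomp_grid <- function(varcomp) {
  varcomp |>
    dplyr::group_by(.data$scenario, .data$m, .data$variance, .data$effect,
                    .data$model) |>
    dplyr::group_modify(function(df, key) summarize_varcomp(df)) |>
    dplyr::ungroup()
}
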