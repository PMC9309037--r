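#' Fit a fixed-effects alternative model
#'
#' Ordinary least squares fits of the fixed-effects model alternatives for
#' the plant-height study, via [stats::lm()]:
#' * `M2`, `M7` — `height ~ temperature` (grouping variable omitted);
#' * `M3` — `height ~ 0 + temperature + mountain` (per-mountain intercepts,
#'   common slope);
#' * `M8` — `height ~ 0 + mountain + temperature:mountain` (per-mountain
#'   intercepts and slopes).
#'
#' @param data Data frame with columns `height`, `temperature`, `mountain`.
#' @param model One of `"M2"`, `"M3"`, `"M7"`, `"M8"`.
#'
#' @return An object of class `ols_fit` wrapping the `lm` fit, with the model
#'   id, coefficient covariance, residual variance and residual degrees of
#'   freedom.  `tidy()` gives the classical per-coefficient t-tests;
#'   for `M8` use [population_slope_bootstrap()] for the population-level
#'   slope.
#' @examples
#' d <- simulate_dataset(scenario_config("B", n_mountains = 3, seed = 5))
#' fit <- fit_ols(d, "M8")
#' tidy(fit)
#' @export
fit_ols <- function(data, model = c("M2", "M3", "M7", "M8")) {
  model <- match.arg(model)
  if (!is.factor(data$mountain)) data$mountain <- factor(data$mountain)
  formula <- switch(model,
    M2 = ,
    M7 = height ~ temperature,
    M3 = height ~ 0 + temperature + mountain,
    M8 = height ~ 0 + mountain + temperature:mountain)
  fit <- lm(formula, data = data)
  if (anyNA(coef(fit))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    abort(paste0("Rank-deficient fixed-effects design; dropped coefficient(s): ",
                 paste(bad, collapse = ", "),
                 ". A mountain needs more observations than per-mountain parameters."))
  }
  structure(
    list(model = model, lm = fit, coefficients = coef(fit),
         coef_cov = vcov(fit), resid_var = summary(fit)$sigma^2,
         df_resid = fit$df.residual, m = nlevels(data$mountain)),
    class = "ols_fit")
}

#' Bootstrap the population-level slope of the per-mountain-slopes model
#'
#' For the fixed-effects model with one slope per mountain (`M8`), the
#' population-level temperature effect is the (weighted) average of the
#' per-mountain slopes.  Its sampling distribution is approximated by a
#' parametric bootstrap from the fitted coefficients: `n_draws` coefficient
#' vectors are drawn from a multivariate normal centred at the estimates
#' with the estimated coefficient covariance; each draw is reduced to the
#' weighted average of the mountain slopes.  The point estimate is the
#' weighted average of the fitted slopes, the standard error the standard
#' deviation of the bootstrap averages, and the two-sided p-value uses a
#' standard-normal reference for estimate / se.
#'
#' @param fit An `M8` [fit_ols()] result.
#' @param n_draws Number of bootstrap draws (at least 100; default 10000).
#' @param weights `"equal"` (each mountain weighted 1/m; broad-sense
#'   inference treats levels symmetrically) or `"by_count"` (weights
#'   proportional to per-mountain sample sizes).
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#'
#' @return A one-row tibble: `coefficient`, `estimate`, `se`, `df` (`Inf`;
#'   normal reference), `statistic`, `p.value`.
#' @examples
#' d <- simulate_dataset(scenario_config("B", n_mountains = 4, seed = 2))
#' d |> fit_ols("M8") |> population_slope_bootstrap(n_draws = 1000, seed = 1)
#' @export
population_slope_bootstrap <- function(fit, n_draws = 10000,
                                       weights = c("equal", "by_count"),
                                       seed = NULL) {
  stopifnot(inherits(fit, "ols_fit"))
  weights <- match.arg(weights)
  if (fit$model != "M8") {
    abort("The population-slope bootstrap requires the per-mountain-slopes model M8.")
  }
  if (n_draws < 100) abort("`n_draws` must be at least 100.")
  idx <- grep(":temperature$|^temperature:", names(fit$coefficients))
  slopes <- fit$coefficients[idx]
  V <- fit$coef_cov[idx, idx, drop = FALSE]
  m <- length(slopes)
  w <- if (weights == "equal") rep(1 / m, m) else {
    ni <- tabulate(fit$lm$model$mountain, m)
    ni / sum(ni)
  }
  R <- tryCatch(chol(V), error = function(e) {
    abort(paste0("Singular slope covariance; a mountain's slope is not ",
                 "identified. Consider `weights = \"by_count\"` or more data."))
  })
  est <- sum(w * slopes)
  draws <- with_seed_if(seed, {
    z <- matrix(rnorm(n_draws * m), n_draws, m)
    sweep(z %*% R, 2, slopes, "+") %*% w
  })
  se <- sd(draws)
  z <- est / se
  tibble::tibble(coefficient = "temperature", estimate = est, se = se,
                 df = Inf, statistic = z, p.value = 2 * pnorm(-abs(z)))
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf("<ols_fit %s> %d coefficients, residual df %d\n",
              x$model, length(x$coefficients), x$df_resid))
  print(x$coefficients)
  invisible(x)
}

#' @rdname fit_ols
#' @param x An `ols_fit` object.
#' @param ... Unused.
#' @export
tidy.ols_fit <- function(x, ...) {
  tab <- summary(x$lm)$coefficients
  tibble::tibble(
    coefficient = rownames(tab), estimate = unname(tab[, 1]),
    se = unname(tab[, 2]), df = x$df_resid,
    statistic = unname(tab[, 3]), p.value = unname(tab[, 4]))
}

#' @rdname fit_ols
#' @export
glance.ols_fit <- function(x, ...) {
  tibble::tibble(model = x$model, resid_var = x$resid_var,
                 df_resid = x$df_resid, nobs = nrow(x$lm$model),
                 n_mountains = x$m)
}

# Slope test of a fixed-effects fit in the common TestResult schema.
# M2/M3/M7: classical t-test on the shared `temperature` coefficient;
# M8: parametric bootstrap of the population-level slope.
ols_slope_test <- function(fit, n_draws = 1000, weights = "equal",
                           seed = NULL) {
  if (fit$model == "M8") {
    return(population_slope_bootstrap(fit, n_draws = n_draws,
                                      weights = weights, seed = seed))
  }
  td <- tidy(fit)
  td[td$coefficient == "temperature", ]
}
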