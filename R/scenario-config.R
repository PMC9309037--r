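#' Configure a simulated plant-height study
#'
#' A scenario configuration holds every parameter of the data-generating
#' process for the simulated altitudinal study: plants growing on `m`
#' mountains, with plant height responding linearly to a standardized
#' temperature covariate.  Scenario `"A"` lets only the mountain intercepts
#' vary (random intercepts); scenario `"B"` additionally draws a
#' mountain-specific temperature slope, independent of the intercept
#' deviation.
#'
#' Per-mountain sample sizes are unbalanced: each mountain receives a share of
#' the total drawn uniformly on \[0.1, 0.9\] (then normalized), with counts
#' constrained to `count_range`.  The default design places on average
#' `mean_plants_per_mountain = 200` plants on each mountain, with counts
#' between 40 and 360.
#'
#' @param scenario `"A"` (random intercepts) or `"B"` (random intercepts and
#'   independent random slopes).
#' @param n_mountains Number of levels of the grouping variable, at least 2.
#' @param beta_intercept Population-level mean height (cm); 0.4 under the
#'   alternative, 0 under the null.
#' @param beta_slope Population-level height increase per standardized
#'   temperature unit (cm); 0.4 under the alternative, 0 under the null.
#' @param var_intercept Variance of the mountain intercept deviations (cm^2).
#' @param var_slope Variance of the mountain slope deviations (cm^2);
#'   only used in scenario `"B"` (scenario `"A"` forces 0).
#' @param resid_sd Residual standard deviation of plant height (cm).
#' @param mean_plants_per_mountain Expected number of plants per mountain.
#' @param count_range Length-2 integer vector, admissible range of per-mountain
#'   counts.
#' @param counts Optional fixed integer vector of per-mountain counts (length
#'   `n_mountains`).  When supplied, the unbalanced-share mechanism is skipped.
#' @param seed Integer seed making the simulated dataset reproducible, or
#'   `NULL` to draw from the current RNG stream.
#'
#' @return An object of class `scenario_config` (a named list).
#' @seealso [simulate_dataset()]
#' @examples
#' cfg <- scenario_config("B", n_mountains = 4, var_intercept = 0.25,
#'                        var_slope = 0.25, seed = 1)
#' cfg
#' @export
scenario_config <- function(scenario = c("A", "B"),
                            n_mountains = 2L,
                            beta_intercept = 0.4,
                            beta_slope = 0.4,
                            var_intercept = 0.01,
                            var_slope = 0.01,
                            resid_sd = 1,
                            mean_plants_per_mountain = 200L,
                            count_range = c(40L, 360L),
                            counts = NULL,
                            seed = NULL) {
  scenario <- match.arg(scenario)
  m <- as.integer(n_mountains)
  if (is.na(m) || m < 2L) {
    abort("`n_mountains` must be an integer >= 2.")
  }
  if (scenario == "A") var_slope <- 0
  if (var_intercept < 0 || var_slope < 0) {
    abort("Random-effect variances must be non-negative.")
  }
  if (resid_sd < 0) abort("`resid_sd` must be non-negative.")
  count_range <- as.integer(count_range)
  if (length(count_range) != 2L || any(is.na(count_range)) ||
      count_range[1] > count_range[2]) {
    abort("`count_range` must be two ordered integers.")
  }
  if (count_range[1] < 3L) {
    abort("`count_range` minimum must be at least 3 observations per mountain.")
  }
  mean_plants_per_mountain <- as.integer(mean_plants_per_mountain)
  if (mean_plants_per_mountain < count_range[1] ||
      mean_plants_per_mountain > count_range[2]) {
    abort("`mean_plants_per_mountain` must lie within `count_range`.")
  }
  if (!is.null(counts)) {
    counts <- as.integer(counts)
    if (length(counts) != m || any(counts < count_range[1])) {
      abort("`counts` must give one admissible count per mountain.")
    }
  }
  structure(
    list(
      scenario = scenario,
      n_mountains = m,
      beta_intercept = beta_intercept,
      beta_slope = beta_slope,
      var_intercept = var_intercept,
      var_slope = var_slope,
      resid_sd = resid_sd,
      mean_plants_per_mountain = mean_plants_per_mountain,
      count_range = count_range,
      counts = counts,
      total_n = if (is.null(counts)) mean_plants_per_mountain * m
                else sum(counts),
      seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    class = "scenario_config"
  )
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config>\n")
  cat(sprintf("  scenario %s: %d mountains, %d plants in total\n",
              x$scenario, x$n_mountains, x$total_n))
  cat(sprintf("  fixed effects: intercept %.3g cm, slope %.3g cm/unit\n",
              x$beta_intercept, x$beta_slope))
  cat(sprintf("  random-effect variances: intercept %.3g, slope %.3g cm^2\n",
              x$var_intercept, x$var_slope))
  cat(sprintf("  residual sd: %.3g cm; seed: %s\n", x$resid_sd,
              if (is.null(x$seed)) "<none>" else x$seed))
  invisible(x)
}

# Run `expr` under `seed` without disturbing the caller's RNG stream;
# seed = NULL uses (and advances) the current stream.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}
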