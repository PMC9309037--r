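#' Allocate unbalanced per-mountain sample sizes
#'
#' Draws a share of the total sample for each mountain uniformly on
#' \[0.1, 0.9\], normalizes the shares, and converts them to integer counts by
#' largest-remainder rounding.  Draws are repeated until every count falls
#' inside `count_range`, so the expected count per mountain is
#' `total_n / m` while individual mountains remain unbalanced.
#'
#' @param m Number of mountains (>= 2).
#' @param total_n Total number of plants across all mountains.
#' @param count_range Length-2 vector of admissible per-mountain counts.
#' @param shares Optional fixed share vector (proportions summing to 1); when
#'   supplied no shares are drawn and no redraw loop runs (counts are still
#'   checked against `count_range`).
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @param max_tries Redraw budget before giving up.
#'
#' @return Integer vector of length `m` summing to `total_n`.
#' @examples
#' allocate_counts(2, 400, shares = c(0.5, 0.5))
#' allocate_counts(4, 800, seed = 1)
#' @export
allocate_counts <- function(m, total_n, count_range = c(40L, 360L),
                            shares = NULL, seed = NULL, max_tries = 1000L) {
  m <- as.integer(m)
  total_n <- as.integer(total_n)
  if (total_n < m * max(count_range[1], 3L)) {
    abort(sprintf(
      "Infeasible allocation: total_n = %d cannot give %d mountains at least %d plants each.",
      total_n, m, max(count_range[1], 3L)))
  }
  with_seed_if(seed, {
    if (!is.null(shares)) {
      stopifnot(length(shares) == m)
      counts <- largest_remainder(shares / sum(shares), total_n)
      if (any(counts < count_range[1]) || any(counts > count_range[2])) {
        abort("Fixed `shares` produce counts outside `count_range`.")
      }
      return(counts)
    }
    for (i in seq_len(max_tries)) {
      raw <- runif(m, 0.1, 0.9)
      counts <- largest_remainder(raw / sum(raw), total_n)
      if (all(counts >= count_range[1]) && all(counts <= count_range[2])) {
        return(counts)
      }
    }
    abort("Could not draw admissible per-mountain counts within the redraw budget.")
  })
}

# Integer apportionment of total_n by proportions p (largest remainder).
largest_remainder <- function(p, total_n) {
  raw <- p * total_n
  counts <- floor(raw)
  short <- total_n - sum(counts)
  if (short > 0) {
    up <- order(raw - counts, decreasing = TRUE)[seq_len(short)]
    counts[up] <- counts[up] + 1
  }
  as.integer(counts)
}

#' Draw mean-zero normal random-effect deviations
#'
#' @param m Number of levels.
#' @param variance Variance of the deviations (cm^2); 0 gives exact zeros.
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#'
#' @return Numeric vector of `m` i.i.d. N(0, variance) draws.
#' @examples
#' sample_random_effects(5, 0.25, seed = 1)
#' @export
sample_random_effects <- function(m, variance, seed = NULL) {
  if (variance < 0) abort("`variance` must be non-negative.")
  with_seed_if(seed, sqrt(variance) * rnorm(m))
}

#' Simulate one plant-height dataset
#'
#' Generates heights from the hierarchical linear model
#' \deqn{H_{ij} = (\beta_0 + b_{0i}) + (\beta_1 + b_{1i}) T_{ij} + \varepsilon_{ij}}
#' with mountain deviations \eqn{b_{0i} \sim N(0, \sigma^2_{b0})},
#' \eqn{b_{1i} \sim N(0, \sigma^2_{b1})} drawn independently (scenario A fixes
#' \eqn{\sigma^2_{b1} = 0}), and residuals \eqn{\varepsilon_{ij} \sim N(0, \sigma_e^2)}.
#' The temperature covariate is drawn i.i.d. standard normal and z-scored
#' within the dataset.  All draws come from a single RNG stream seeded by
#' `config$seed`, so regeneration with the same configuration is bit-identical.
#'
#' @param config A [scenario_config()].
#'
#' @return A tibble with columns `height` (cm), `temperature` (standardized),
#'   and `mountain` (factor with levels `1..m`), rows grouped by mountain.
#'   The configuration, per-mountain counts and true random effects are
#'   attached as attributes `config`, `counts`, `ranef`.
#' @examples
#' simulate_dataset(scenario_config("A", n_mountains = 3, seed = 42))
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  m <- config$n_mountains
  with_seed_if(config$seed, {
    counts <- if (!is.null(config$counts)) config$counts else
      allocate_counts(m, config$total_n, config$count_range)
    n <- sum(counts)
    temp <- rnorm(n)
    temp <- as.numeric(scale(temp))
    b0 <- sqrt(config$var_intercept) * rnorm(m)
    b1 <- sqrt(config$var_slope) * rnorm(m)
    g <- rep.int(seq_len(m), counts)
    height <- (config$beta_intercept + b0[g]) +
      (config$beta_slope + b1[g]) * temp +
      config$resid_sd * rnorm(n)
    out <- tibble::tibble(
      height = height,
      temperature = temp,
      mountain = factor(g, levels = seq_len(m))
    )
    attr(out, "config") <- config
    attr(out, "counts") <- counts
    attr(out, "ranef") <- tibble::tibble(
      mountain = factor(seq_len(m)), b_intercept = b0, b_slope = b1)
    out
  })
}

#' Sample a random study design for the sweep
#'
#' Draws one study-design point as in the design sweep: number of mountains
#' uniform on \{2, ..., 20\}, a common random-effect variance uniform on
#' \[1e-4, 4\], observations per mountain 10 to 500 times the number of
#' mountains, and unbalanced per-mountain shares uniform on \[0.1, 0.9\]
#' (normalized; redrawn until every mountain receives at least 3 plants).
#' The unbalance proxy is the difference between the largest and smallest
#' share.
#'
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#'
#' @return A one-row tibble with columns `m`, `var_random`,
#'   `obs_per_level_factor`, `total_n`, `unbalance_proxy`, `seed`, and a
#'   list-column `counts` of per-mountain counts.
#' @examples
#' sample_design_point(seed = 7)
#' @export
sample_design_point <- function(seed = NULL) {
  with_seed_if(seed, {
    m <- sample(2:20, 1L)
    var_random <- runif(1L, 1e-4, 4)
    factor_n <- sample(10:500, 1L)
    total_n <- factor_n * m
    repeat {
      raw <- runif(m, 0.1, 0.9)
      shares <- raw / sum(raw)
      counts <- largest_remainder(shares, total_n)
      if (all(counts >= 3L)) break
    }
    tibble::tibble(
      m = m,
      var_random = var_random,
      obs_per_level_factor = factor_n,
      total_n = total_n,
      unbalance_proxy = max(shares) - min(shares),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
      level_shares = list(shares),
      counts = list(counts)
    )
  })
}
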