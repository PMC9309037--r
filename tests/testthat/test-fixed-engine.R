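test_that("fixed-effects fits recover noiseless per-mountain coefficients", {
  ints <- c(1, 2, 3)
  slps <- c(0.5, -0.2, 0.9)
  d <- tibble::tibble(
    temperature = rep(seq(-2, 2, length.out = 10), 3),
    mountain = factor(rep(1:3, each = 10)),
    height = ints[rep(1:3, each = 10)] +
      slps[rep(1:3, each = 10)] * temperature)
  fit <- suppressWarnings(fit_ols(d, "M8"))  # perfect fit warns
  expect_length(fit$coefficients, 2 * 3)
  expect_equal(unname(fit$coefficients[1:3]), ints, tolerance = 1e-10)
  expect_equal(unname(fit$coefficients[4:6]), slps, tolerance = 1e-10)

  # common-slope model has m intercepts + 1 slope
  expect_length(suppressWarnings(fit_ols(d, "M3"))$coefficients, 3 + 1)

  # pooled model on a single mountain is simple regression
  d1 <- d[d$mountain == "1", ]
  f2 <- suppressWarnings(fit_ols(d1, "M2"))  # perfect fit warns
  expect_equal(unname(coef(f2$lm)["temperature"]),
               cov(d1$temperature, d1$height) / var(d1$temperature),
               tolerance = 1e-10)
})

test_that("rank-deficient per-mountain designs are rejected with a message", {
  d <- tibble::tibble(
    temperature = c(seq(-1, 1, length.out = 10), 0.3),
    mountain = factor(c(rep(1, 10), 2)),
    height = rnorm(11))
  expect_error(fit_ols(d, "M8"), "Rank-deficient")
})

test_that("population-slope bootstrap matches the closed-form linear combination", {
  n_checked <- 0
  for (s in 1:50) {
    d <- simulate_dataset(scenario_config(
      "B", n_mountains = 2 + (s %% 4), var_intercept = 0.25,
      var_slope = 0.25, mean_plants_per_mountain = 60L,
      count_range = c(10L, 360L), seed = 1200 + s))
    fit <- fit_ols(d, "M8")
    bt <- population_slope_bootstrap(fit, n_draws = 10000, seed = s)
    idx <- grep("temperature", names(fit$coefficients))
    m <- length(idx)
    w <- rep(1 / m, m)
    se_exact <- sqrt(drop(t(w) %*% fit$coef_cov[idx, idx] %*% w))
    expect_equal(bt$estimate, sum(w * fit$coefficients[idx]),
                 tolerance = 1e-10)
    expect_lt(abs(bt$se - se_exact) / se_exact, 0.05)
    n_checked <- n_checked + 1
  }
  expect_equal(n_checked, 50)
})

test_that("bootstrap is reproducible, symmetric, and degenerates correctly", {
  d <- simulate_dataset(scenario_config("B", n_mountains = 4, seed = 71))
  fit <- fit_ols(d, "M8")
  expect_identical(population_slope_bootstrap(fit, 1000, seed = 5),
                   population_slope_bootstrap(fit, 1000, seed = 5))
  expect_error(population_slope_bootstrap(fit, n_draws = 10), "at least 100")
  expect_error(population_slope_bootstrap(fit_ols(d, "M3")), "M8")

  # flipping the response flips the estimate, leaves se and p unchanged
  dneg <- dplyr::mutate(d, height = -height)
  fitn <- fit_ols(dneg, "M8")
  b1 <- population_slope_bootstrap(fit, 2000, seed = 9)
  b2 <- population_slope_bootstrap(fitn, 2000, seed = 9)
  expect_equal(b2$estimate, -b1$estimate, tolerance = 1e-10)
  expect_equal(b2$se, b1$se, tolerance = 1e-6)
  expect_equal(b2$p.value, b1$p.value, tolerance = 1e-6)

  # near-zero coefficient covariance: estimate = common slope, se -> 0
  dexact <- tibble::tibble(
    temperature = rep(seq(-2, 2, length.out = 12), 2),
    mountain = factor(rep(1:2, each = 12)),
    height = 1 + 0.5 * temperature +
      withr::with_seed(3, rnorm(24, 0, 1e-7)))
  bt <- population_slope_bootstrap(suppressWarnings(fit_ols(dexact, "M8")),
                                   1000, seed = 1)
  expect_equal(bt$estimate, 0.5, tolerance = 1e-5)
  expect_lt(bt$se, 1e-6)

  # by-count weights shift the estimate towards large mountains
  bw <- population_slope_bootstrap(fit, 1000, weights = "by_count", seed = 5)
  idx <- grep("temperature", names(fit$coefficients))
  ni <- tabulate(d$mountain)
  expect_equal(bw$estimate,
               sum(ni / sum(ni) * fit$coefficients[idx]), tolerance = 1e-10)
})

test_that("the common-slope model is the within-mountain estimator", {
  d <- simulate_dataset(scenario_config("B", n_mountains = 5, seed = 72))
  fit <- fit_ols(d, "M3")
  slope_m3 <- unname(fit$coefficients["temperature"])
  # oracle: centre height and temperature within mountains, regress without
  # an intercept
  dc <- d |>
    dplyr::group_by(mountain) |>
    dplyr::mutate(hc = height - mean(height),
                  tc = temperature - mean(temperature)) |>
    dplyr::ungroup()
  expect_equal(slope_m3, sum(dc$hc * dc$tc) / sum(dc$tc^2),
               tolerance = 1e-10)
})

test_that("fixed and mixed slope tests agree on balanced random-intercept data", {
  for (s in 1:3) {
    d <- balanced_oneway_data(m = 5, n0 = 40, sd_b = 0.5, seed = 1500 + s)
    m3 <- tidy(fit_ols(d, "M3"))
    m3 <- m3[m3$coefficient == "temperature", ]
    m4fit <- fit_lmm(d, "M4")
    if (m4fit$singular) next
    m4 <- satterthwaite_test(m4fit, "temperature")
    expect_equal(m4$estimate, m3$estimate, tolerance = 1e-8)
    expect_lt(abs(m4$p.value - m3$p.value) / m3$p.value, 0.1)
  }
})
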