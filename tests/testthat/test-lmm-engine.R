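test_that("profiled criterion matches a dense-matrix oracle for every structure", {
  for (s in 1:4) {
    d <- simulate_dataset(scenario_config(
      "B", n_mountains = 5, var_intercept = 0.25, var_slope = 0.25,
      mean_plants_per_mountain = 8L, count_range = c(3L, 40L),
      seed = 100 + s))
    thetas <- list(M4 = 0.7, M10 = c(0.5, 0.3), M11 = c(0.5, -0.2, 0.4))
    for (model in names(thetas)) {
      for (est in c("REML", "ML")) {
        expect_equal(
          lmm_profiled_criterion(d, model, thetas[[model]], est),
          as.numeric(dense_criterion(d, thetas[[model]],
                                     levelsim:::lmm_structure(model), est)),
          tolerance = 1e-8)
      }
    }
  }
})

test_that("criterion at theta = 0 reduces to the OLS restricted likelihood", {
  d <- simulate_dataset(scenario_config("A", n_mountains = 4, seed = 31))
  expect_equal(lmm_profiled_criterion(d, "M4", 0),
               as.numeric(ols_restricted_criterion(d)), tolerance = 1e-10)
  expect_equal(lmm_profiled_criterion(d, "M10", c(0, 0), "ML"),
               as.numeric(ols_restricted_criterion(d, "ML")),
               tolerance = 1e-10)
})

test_that("criterion is invariant to row permutation", {
  d <- simulate_dataset(scenario_config("B", n_mountains = 3, seed = 8))
  dp <- d[withr::with_seed(1, sample(nrow(d))), ]
  expect_equal(lmm_profiled_criterion(d, "M10", c(0.4, 0.2)),
               lmm_profiled_criterion(dp, "M10", c(0.4, 0.2)),
               tolerance = 1e-10)
})

test_that("REML on balanced one-way layouts equals the ANOVA closed form", {
  n_checked <- 0
  for (s in 1:50) {
    d <- balanced_oneway_data(m = 6, n0 = 30, sd_b = 0.4, seed = 400 + s)
    oracle <- balanced_oneway_oracle(d)
    if (!oracle$anova_valid) next
    n_checked <- n_checked + 1
    fit <- fit_lmm(d, "M4")
    expect_equal(fit$sigma2_resid, oracle$sigma2_e, tolerance = 1e-6)
    expect_equal(fit$varcomp$sigma2_intercept, oracle$sigma2_b,
                 tolerance = 1e-6)
    expect_equal(fit$criterion, oracle$criterion, tolerance = 1e-8)
  }
  expect_gt(n_checked, 40)
})

test_that("fits agree with the lme4/lmerTest reference on shared data", {
  skip_if_not_installed("lme4")
  skip_if_not_installed("lmerTest")
  forms <- list(
    M4 = height ~ temperature + (1 | mountain),
    M10 = height ~ temperature + (1 | mountain) +
      (0 + temperature | mountain),
    M11 = height ~ temperature + (temperature | mountain))
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore")
  for (s in 1:4) {
    d <- simulate_dataset(scenario_config(
      "B", n_mountains = 6, var_intercept = 0.25, var_slope = 0.25,
      mean_plants_per_mountain = 50L, count_range = c(3L, 300L),
      seed = 600 + s))
    for (model in names(forms)) {
      for (est in c("REML", "ML")) {
        fit <- fit_lmm(d, model, est)
        ref <- suppressMessages(lmerTest::lmer(
          forms[[model]], data = d, REML = est == "REML", control = ctrl))
        expect_equal(fit$criterion,
                     if (est == "REML") lme4::REMLcrit(ref)
                     else as.numeric(deviance(ref)),
                     tolerance = 1e-6)
        expect_equal(unname(fit$beta), unname(lme4::fixef(ref)),
                     tolerance = 1e-5)
        expect_equal(fit$sigma2_resid, sigma(ref)^2,
                     tolerance = 1e-4)
        expect_identical(fit$singular, lme4::isSingular(ref))
        if (est == "REML" && !fit$singular) {
          st <- satterthwaite_test(fit, "temperature")
          ct <- coef(summary(ref))["temperature", ]
          expect_equal(st$estimate, unname(ct["Estimate"]), tolerance = 1e-5)
          expect_equal(st$se, unname(ct["Std. Error"]), tolerance = 1e-4)
          expect_equal(st$df, unname(ct["df"]), tolerance = 0.02)
          expect_equal(st$p.value, unname(ct["Pr(>|t|)"]), tolerance = 1e-3)
        }
      }
    }
  }
})

test_that("ML shrinks the residual variance relative to REML", {
  # no-random-effect limit: both estimators land on the boundary and the
  # ratio of residual-variance estimates is exactly (n - p) / n
  d0 <- simulate_dataset(scenario_config(
    "A", n_mountains = 4, var_intercept = 0, seed = 57))
  fr <- fit_lmm(d0, "M4", "REML")
  fm <- fit_lmm(d0, "M4", "ML")
  expect_true(fr$singular && fm$singular)
  expect_equal(fm$sigma2_resid / fr$sigma2_resid,
               (nrow(d0) - 2) / nrow(d0), tolerance = 1e-8)

  for (s in 1:10) {
    d <- simulate_dataset(scenario_config(
      "B", n_mountains = 4, var_intercept = 0.25, var_slope = 0.25,
      seed = 700 + s))
    # approximate inequality: boundary estimates can perturb it at ~1e-4
    expect_lte(fit_lmm(d, "M10", "ML")$sigma2_resid,
               fit_lmm(d, "M10", "REML")$sigma2_resid + 1e-3)
  }
})

test_that("boundary fits are classified as singular", {
  expect_true(is_singular(fake_lmm_fit(c(0, 0.3), "diag")))
  expect_false(is_singular(fake_lmm_fit(c(0.5, 0.3), "diag")))
  # correlation 0.99999 with tolerance 1e-4
  rho <- 0.99999
  expect_true(is_singular(fake_lmm_fit(c(0.5, 0.4 * rho,
                                         0.4 * sqrt(1 - rho^2)), "corr")))
  # moderate correlation 0.2 is interior
  rho <- 0.2
  expect_false(is_singular(fake_lmm_fit(c(0.5, 0.4 * rho,
                                          0.4 * sqrt(1 - rho^2)), "corr")))
  # a dataset with no between-mountain variance and tiny noise
  dflat <- tibble::tibble(
    temperature = rep(seq(-1, 1, length.out = 20), 3),
    height = 1 + 0.5 * temperature + withr::with_seed(2, rnorm(60, 0, 1e-3)),
    mountain = factor(rep(1:3, each = 20)))
  fit <- fit_lmm(dflat, "M4")
  expect_true(fit$singular)
  expect_lt(fit$varcomp$sigma2_intercept, 1e-8)
})

test_that("Satterthwaite df reproduce the classical balanced-case values", {
  # balanced random-intercept data: intercept df ~ m - 1
  for (s in 1:5) {
    d <- balanced_oneway_data(m = 6, n0 = 40, sd_b = 0.6, seed = 800 + s)
    fit <- fit_lmm(d, "M4")
    if (fit$singular) next
    st <- satterthwaite_test(fit, "(Intercept)")
    expect_equal(st$df, 5, tolerance = 0.03)
    # slope is orthogonal to the grouping here: df ~ residual df
    expect_equal(satterthwaite_test(fit, "temperature")$df,
                 nrow(d) - 2, tolerance = 0.05)
  }
})

test_that("a variance estimate at zero recovers the OLS slope test", {
  d <- simulate_dataset(scenario_config(
    "A", n_mountains = 4, var_intercept = 0, seed = 58))
  fit <- fit_lmm(d, "M4")
  expect_true(fit$singular)
  st <- satterthwaite_test(fit, "temperature")
  ols <- summary(lm(height ~ temperature, data = d))$coefficients
  expect_equal(st$estimate, ols["temperature", "Estimate"],
               tolerance = 1e-8)
  expect_equal(st$df, nrow(d) - 2, tolerance = 0.1)
  expect_equal(st$p.value, ols["temperature", "Pr(>|t|)"], tolerance = 1e-3)
})

test_that("negating the response flips the estimate but not the test", {
  d <- simulate_dataset(scenario_config("B", n_mountains = 5, seed = 57))
  fit <- fit_lmm(d, "M10")
  dneg <- dplyr::mutate(d, height = -height)
  fitn <- fit_lmm(dneg, "M10")
  st <- satterthwaite_test(fit, "temperature")
  stn <- satterthwaite_test(fitn, "temperature")
  expect_equal(stn$estimate, -st$estimate, tolerance = 1e-6)
  expect_equal(abs(stn$statistic), abs(st$statistic), tolerance = 1e-6)
  expect_equal(stn$df, st$df, tolerance = 1e-4)
  expect_equal(stn$p.value, st$p.value, tolerance = 1e-6)
})

test_that("null p-values of the correctly specified model are uniform", {
  g <- run_grid(run_config("A", m_values = 6, variances = 0.25,
                           effect = "null", models = "M4", n_reps = 1000,
                           master_seed = 4242))
  pv <- g$results$p.value[!g$results$singular]
  expect_gt(length(pv), 900)
  ks <- suppressWarnings(stats::ks.test(pv, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("REML recovers the generating variances with many levels", {
  est <- purrr::map_dfr(1:40, function(s) {
    d <- simulate_dataset(scenario_config(
      "B", n_mountains = 50, var_intercept = 0.25, var_slope = 0.25,
      mean_plants_per_mountain = 100L, count_range = c(20L, 500L),
      seed = 900 + s))
    glance(fit_lmm(d, "M10"))
  })
  expect_lt(abs(median(est$sigma2_intercept) - 0.25) / 0.25, 0.1)
  expect_lt(abs(median(est$sigma2_slope) - 0.25) / 0.25, 0.1)
  expect_lt(abs(median(est$sigma2_resid) - 1), 0.05)
})

test_that("degenerate designs raise informative errors", {
  d <- simulate_dataset(scenario_config("A", n_mountains = 3, seed = 3))
  dconst <- dplyr::mutate(d, temperature = 1)
  expect_error(fit_lmm(dconst, "M4"), "collinear")
  dmiss <- dplyr::filter(d, mountain != "2")
  expect_error(fit_lmm(dmiss, "M4"), "level")
  expect_error(lmm_profiled_criterion(d, "M4", c(1, 2)), "length")
  expect_error(lmm_profiled_criterion(d, "M4", -0.5), "non-negative")
  expect_error(fit_lmm(d, "M12"), "Unknown mixed-model id")
})
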