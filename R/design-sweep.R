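#' Pinball (check) loss
#'
#' Loss minimized by quantile regression at level `tau`:
#' \eqn{\rho_\tau(r) = r(\tau - 1[r < 0])}.
#'
#' @param residuals Numeric vector of residuals (observed minus fitted).
#' @param tau Quantile level in (0, 1).
#' @return Mean pinball loss.
#' @export
pinball_loss <- function(residuals, tau = 0.5) {
  mean(residuals * (tau - (residuals < 0)))
}

#' Run the random study-design sweep
#'
#' Samples random study designs (see [sample_design_point()]) and, for each,
#' estimates the type I error rate and power of the population-level slope
#' for the correctly specified scenario-B mixed model (`M10`, REML,
#' Satterthwaite test, non-singular fits only) and its fixed-effects
#' counterpart (`M8`, population-slope bootstrap, all datasets).  Datasets
#' are simulated from the scenario-B generator with intercept and slope
#' variances both equal to the design's `var_random`, per-mountain counts
#' fixed by the design's shares, and slope 0 (type I error) or 0.4 cm
#' (power).  Simulation continues until `fits_per_point` non-singular mixed
#' fits are collected or the retry budget (`retry_factor * fits_per_point`
#' datasets) is exhausted, in which case the point is flagged.
#'
#' @param n_points Number of design points (>= 10).
#' @param fits_per_point Target number of non-singular mixed fits per point.
#' @param master_seed Integer master seed.
#' @param alpha Significance level.
#' @param retry_factor Retry budget multiplier for non-singular fits.
#' @param bootstrap_draws Bootstrap draws for the `M8` population slope.
#' @param effects Which rates to estimate: `"null"` (type I error), `"weak"`
#'   (power), or both (default).
#'
#' @return A tibble with one row per design point x model family
#'   (`"mixed"`, `"fixed"`): design covariates (`m`, `var_random`,
#'   `total_n`, `unbalance_proxy`), `type_I`, `power`, `n_fits_used`,
#'   `flagged`.
#' @examples
#' \donttest{
#' sw <- run_sweep(n_points = 10, fits_per_point = 20, master_seed = 1)
#' }
#' @export
run_sweep <- function(n_points = 200, fits_per_point = 200, master_seed = 1L,
                      alpha = 0.05, retry_factor = 8, bootstrap_draws = 1000,
                      effects = c("null", "weak")) {
  if (n_points < 10) abort("`n_points` must be at least 10.")
  effects <- match.arg(effects, several.ok = TRUE)
  rows <- vector("list", n_points)
  for (i in seq_len(n_points)) {
    point_seed <- master_seed + i * 100000L
    pt <- sample_design_point(seed = point_seed)
    counts <- pt$counts[[1]]
    rates <- list()
    for (ef in effects) {
      beta <- if (ef == "null") 0 else 0.4
      base_cfg <- scenario_config(
        scenario = "B", n_mountains = pt$m,
        beta_intercept = beta, beta_slope = beta,
        var_intercept = pt$var_random, var_slope = pt$var_random,
        resid_sd = 1,
        mean_plants_per_mountain = max(3L, min(round(pt$total_n / pt$m),
                                               max(counts))),
        count_range = c(3L, max(counts)), counts = counts)
      budget <- ceiling(retry_factor * fits_per_point)
      p_mixed <- numeric(0)
      p_fixed <- numeric(0)
      r <- 0L
      while (length(p_mixed) < fits_per_point && r < budget) {
        r <- r + 1L
        seed_r <- point_seed + (if (ef == "null") 0L else 50000L) + r
        withr::with_seed(seed_r, {
          data <- simulate_dataset(base_cfg)
          mfit <- fit_lmm(data, "M10")
          if (!mfit$singular) {
            p_mixed <- c(p_mixed,
                         satterthwaite_test(mfit, "temperature")$p.value)
          }
          ffit <- fit_ols(data, "M8")
          p_fixed <- c(p_fixed,
                       population_slope_bootstrap(
                         ffit, n_draws = bootstrap_draws)$p.value)
        })
      }
      rates[[ef]] <- list(
        mixed = mean(p_mixed < alpha), fixed = mean(p_fixed < alpha),
        n_mixed = length(p_mixed), n_fixed = length(p_fixed),
        flagged = length(p_mixed) < fits_per_point)
    }
    pick <- function(ef, fam) {
      if (is.null(rates[[ef]])) NA_real_ else rates[[ef]][[fam]]
    }
    nn <- function(fam) {
      min(vapply(rates, `[[`, numeric(1), fam), na.rm = TRUE)
    }
    rows[[i]] <- tibble::tibble(
      point = i, m = pt$m, var_random = pt$var_random,
      total_n = pt$total_n, unbalance_proxy = pt$unbalance_proxy,
      model = c("mixed", "fixed"),
      type_I = c(pick("null", "mixed"), pick("null", "fixed")),
      power = c(pick("weak", "mixed"), pick("weak", "fixed")),
      n_fits_used = c(nn("n_mixed"), nn("n_fixed")),
      flagged = c(any(vapply(rates, `[[`, logical(1), "flagged")), FALSE))
  }
  out <- dplyr::bind_rows(rows)
  flagged <- unique(out$point[out$flagged])
  if (length(flagged)) {
    warn(sprintf(
      "%d design point(s) did not reach the non-singular fit target and are flagged: %s",
      length(flagged), paste(head(flagged, 10), collapse = ", ")))
  }
  out
}

#' Penalized additive quantile regression with splines
#'
#' Fits an additive model for the `tau`-quantile of a response by minimizing
#' the pinball loss plus a second-order difference (smoothness) penalty on
#' cubic B-spline coefficients, one spline block per covariate.  The
#' minimization uses iteratively reweighted least squares on a smoothed
#' absolute residual; the penalty weight is chosen by k-fold
#' cross-validated pinball loss over a log-spaced grid.  Covariates are
#' standardized internally; constant covariates get a constant partial
#' effect (with a warning).
#'
#' @param data A data frame (e.g. a [run_sweep()] result).
#' @param response Name of the response column (a rate in \[0, 1\]).
#' @param covariates Character vector of covariate column names.
#' @param tau Quantile level in (0, 1) (default 0.5, the median).
#' @param knots Basis dimension per covariate (>= 4).
#' @param lambda Penalty weight; `NULL` selects by cross-validation.
#' @param lambda_grid Candidate penalties for cross-validation.
#' @param n_folds Cross-validation folds.
#' @param cv_seed Seed for the fold assignment.
#'
#' @return An object of class `quantile_spline` with [predict()] and
#'   [partial_effects()] methods.
#' @examples
#' d <- tibble::tibble(x = seq(0, 2 * pi, length.out = 200),
#'                     y = sin(x) + rnorm(200, 0, 0.1))
#' fit <- fit_quantile_spline(d, "y", "x", lambda = 1)
#' @export
fit_quantile_spline <- function(data, response, covariates, tau = 0.5,
                                knots = 10, lambda = NULL,
                                lambda_grid = 10^seq(-4, 2, by = 1),
                                n_folds = 5, cv_seed = 1L) {
  if (tau <= 0 || tau >= 1) abort("`tau` must lie in (0, 1).")
  if (knots < 4) abort("`knots` must be at least 4.")
  if (nrow(data) < 50) abort("At least 50 observations are required.")
  y <- data[[response]]
  blocks <- list()
  for (cv in covariates) {
    x <- data[[cv]]
    if (sd(x) < 1e-12) {
      warn(sprintf("Covariate '%s' is constant; its curve is constant.", cv))
      blocks[[cv]] <- list(constant = TRUE, center = mean(x))
      next
    }
    xs <- (x - mean(x)) / sd(x)
    B <- splines::bs(xs, df = knots, degree = 3)
    blocks[[cv]] <- list(
      constant = FALSE, mean = mean(x), sd = sd(x),
      knots = attr(B, "knots"), boundary = attr(B, "Boundary.knots"),
      col_means = colMeans(B), basis = sweep(B, 2, colMeans(B)))
  }
  active <- names(blocks)[!vapply(blocks, `[[`, logical(1), "constant")]
  if (!length(active)) abort("All covariates are constant.")
  X <- cbind(`(Intercept)` = 1,
             do.call(cbind, lapply(blocks[active], `[[`, "basis")))
  # block-diagonal second-difference penalty (intercept unpenalized)
  P <- matrix(0, ncol(X), ncol(X))
  off <- 1L
  for (cv in active) {
    k <- ncol(blocks[[cv]]$basis)
    D <- diff(diag(k), differences = 2)
    idx <- off + seq_len(k)
    P[idx, idx] <- crossprod(D)
    off <- off + k
  }
  if (is.null(lambda)) {
    folds <- withr::with_seed(cv_seed,
                              sample(rep_len(seq_len(n_folds), nrow(X))))
    cv_loss <- vapply(lambda_grid, function(lam) {
      losses <- vapply(seq_len(n_folds), function(f) {
        tr <- folds != f
        th <- pinball_irls(X[tr, , drop = FALSE], y[tr], P, lam, tau)
        pinball_loss(y[!tr] - drop(X[!tr, , drop = FALSE] %*% th), tau)
      }, numeric(1))
      mean(losses)
    }, numeric(1))
    lambda <- lambda_grid[which.min(cv_loss)]
  }
  theta <- pinball_irls(X, y, P, lambda, tau)
  fitted <- drop(X %*% theta)
  structure(
    list(coef = theta, blocks = blocks, active = active, tau = tau,
         lambda = lambda, response = response, covariates = covariates,
         train_loss = pinball_loss(y - fitted, tau), fitted = fitted),
    class = "quantile_spline")
}

# IRLS for the smoothed pinball objective: weights tau/(1-tau) over |r|.
pinball_irls <- function(X, y, P, lambda, tau, max_iter = 200, tol = 1e-8) {
  delta <- 1e-4 * max(sd(y), 1e-8)
  theta <- solve(crossprod(X) + lambda * P + 1e-10 * diag(ncol(X)),
                 crossprod(X, y))
  for (it in seq_len(max_iter)) {
    r <- y - drop(X %*% theta)
    w <- ifelse(r > 0, tau, 1 - tau) / pmax(abs(r), delta)
    XtW <- t(X * w)
    new_theta <- solve(XtW %*% X + lambda * P + 1e-10 * diag(ncol(X)),
                       XtW %*% y)
    if (max(abs(new_theta - theta)) < tol * (1 + max(abs(theta)))) {
      theta <- new_theta
      break
    }
    theta <- new_theta
  }
  drop(theta)
}

#' @export
print.quantile_spline <- function(x, ...) {
  cat(sprintf(
    "<quantile_spline> tau = %.2f, lambda = %.3g, training pinball loss %.4g\n",
    x$tau, x$lambda, x$train_loss))
  cat("  covariates:", paste(x$covariates, collapse = ", "), "\n")
  invisible(x)
}

#' @export
predict.quantile_spline <- function(object, newdata, ...) {
  n <- nrow(newdata)
  eta <- rep(object$coef[1], n)
  off <- 1L
  for (cv in object$active) {
    bl <- object$blocks[[cv]]
    k <- length(bl$col_means)
    xs <- (newdata[[cv]] - bl$mean) / bl$sd
    xs <- pmin(pmax(xs, bl$boundary[1]), bl$boundary[2])
    B <- splines::bs(xs, knots = bl$knots, degree = 3,
                     Boundary.knots = bl$boundary)
    B <- sweep(B, 2, bl$col_means)
    eta <- eta + drop(B %*% object$coef[off + seq_len(k)])
    off <- off + k
  }
  eta
}

#' Partial-effect curves of a fitted quantile spline
#'
#' Evaluates each covariate's additive contribution on a grid over its
#' training range, holding the other covariates at their means (their
#' centred contributions then vanish, so the curve is the intercept plus
#' the covariate's own spline term).
#'
#' @param object A [fit_quantile_spline()] result.
#' @param grid_n Grid points per covariate.
#' @return A tibble: `covariate`, `x`, `effect`.
#' @export
partial_effects <- function(object, grid_n = 100) {
  stopifnot(inherits(object, "quantile_spline"))
  rows <- list()
  off <- 1L
  for (cv in object$covariates) {
    bl <- object$blocks[[cv]]
    if (isTRUE(bl$constant)) {
      rows[[cv]] <- tibble::tibble(
        covariate = cv, x = rep(bl$center, grid_n),
        effect = rep(object$coef[1], grid_n))
      next
    }
    k <- length(bl$col_means)
    xg <- seq(bl$boundary[1], bl$boundary[2], length.out = grid_n)
    B <- splines::bs(xg, knots = bl$knots, degree = 3,
                     Boundary.knots = bl$boundary)
    B <- sweep(B, 2, bl$col_means)
    rows[[cv]] <- tibble::tibble(
      covariate = cv, x = xg * bl$sd + bl$mean,
      effect = object$coef[1] + drop(B %*% object$coef[off + seq_len(k)]))
    off <- off + k
  }
  dplyr::bind_rows(rows)
}
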