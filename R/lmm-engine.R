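#' @name lmm_engine
#' @title Linear mixed-model engine
#'
#' @description
#' Mixed models for the simulated plant-height study are fitted by profiled
#' (restricted) maximum likelihood.  The random-effect covariance is
#' parameterized through its relative Cholesky factor \eqn{\Lambda(\theta)},
#' the Cholesky factor of the per-mountain covariance divided by the residual
#' variance, so the marginal covariance of one mountain's observations is
#' \eqn{\sigma_e^2 (I + Z_i \Lambda \Lambda' Z_i')}.  Both the fixed effects
#' and the residual variance are profiled out in closed form; the criterion
#' (\eqn{-2} log (restricted) likelihood) is evaluated from per-mountain
#' sufficient statistics via the Woodbury identity, so a criterion evaluation
#' costs O(m) regardless of the number of plants.
#'
#' Supported model structures (response `height`, covariate `temperature`,
#' grouping factor `mountain`):
#' * `M4`, `M9` — random intercept per mountain;
#' * `M5`, `M10` — independent random intercept and random temperature slope;
#' * `M11` — correlated random intercept and slope.
NULL

lmm_models <- c(M4 = "int", M9 = "int", M5 = "diag", M10 = "diag",
                M11 = "corr")

lmm_structure <- function(model) {
  model <- as.character(model)
  if (!model %in% names(lmm_models)) {
    abort(sprintf(
      "Unknown mixed-model id '%s' (expected one of %s).",
      model, paste(names(lmm_models), collapse = ", ")))
  }
  unname(lmm_models[model])
}

n_theta <- function(structure) c(int = 1L, diag = 2L, corr = 3L)[[structure]]

# Per-mountain sufficient statistics for models with fixed effects
# [1, temperature] and random terms spanned by the same columns.
lmm_suffstats <- function(data) {
  req <- c("height", "temperature", "mountain")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols)) {
    abort(paste0("`data` lacks column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  g <- data$mountain
  if (!is.factor(g)) g <- factor(g)
  gi <- as.integer(g)
  m <- nlevels(g)
  t <- as.numeric(data$temperature)
  y <- as.numeric(data$height)
  n <- length(y)
  ni <- tabulate(gi, m)
  if (any(ni == 0L)) {
    abort("Every mountain level must be present in the data.")
  }
  sums <- unname(rowsum(cbind(t, t * t, y, t * y, y * y), gi,
                        reorder = TRUE))
  tot <- colSums(sums)
  if (tot[2] - tot[1]^2 / n < 1e-10 * max(tot[2], 1)) {
    abort("Rank-deficient design: `temperature` is collinear with the intercept.")
  }
  list(n = n, m = m, p = 2L, ni = ni, levels = levels(g),
       St = sums[, 1], Stt = sums[, 2], Sy = sums[, 3], Sty = sums[, 4],
       St_tot = tot[1], Stt_tot = tot[2], Sy_tot = tot[3], Sty_tot = tot[4],
       Syy = tot[5])
}

# Criterion evaluation. Returns the -2 log (restricted) likelihood, either
# profiled over sigma (sigma = NULL) or at a fixed residual sd. With
# `full = TRUE` also returns beta, its unscaled covariance (G inverse),
# the GLS residual sum of squares and log-determinants.
lmm_eval <- function(ss, theta, structure, estimator = "REML",
                     sigma = NULL, full = FALSE) {
  ni <- ss$ni
  St <- ss$St; Stt <- ss$Stt; Sy <- ss$Sy; Sty <- ss$Sty
  if (structure == "int") {
    l11 <- theta[1]
    Mi <- l11 * l11 * ni + 1
    u1 <- l11 * ni; u2 <- l11 * St; uy <- l11 * Sy
    inv <- 1 / Mi
    D11 <- sum(u1 * u1 * inv); D12 <- sum(u1 * u2 * inv)
    D22 <- sum(u2 * u2 * inv)
    Dy1 <- sum(u1 * uy * inv); Dy2 <- sum(u2 * uy * inv)
    Dyy <- sum(uy * uy * inv)
    logdetV <- sum(log(Mi))
  } else {
    if (structure == "diag") {
      l11 <- theta[1]; l21 <- 0; l22 <- theta[2]
    } else {
      l11 <- theta[1]; l21 <- theta[2]; l22 <- theta[3]
    }
    a <- l11 * ni + l21 * St
    b <- l11 * St + l21 * Stt
    cc <- l22 * St
    d <- l22 * Stt
    M11 <- a * l11 + b * l21 + 1
    M12 <- b * l22
    M22 <- d * l22 + 1
    detM <- M11 * M22 - M12 * M12
    q1 <- l11 * Sy + l21 * Sty
    q2 <- l22 * Sty
    # inv(M) rows reused across the six quadratic forms
    i11 <- M22 / detM; i12 <- -M12 / detM; i22 <- M11 / detM
    t1a <- i11 * a + i12 * cc; t2a <- i12 * a + i22 * cc
    t1b <- i11 * b + i12 * d;  t2b <- i12 * b + i22 * d
    t1q <- i11 * q1 + i12 * q2; t2q <- i12 * q1 + i22 * q2
    D11 <- sum(a * t1a + cc * t2a)
    D12 <- sum(b * t1a + d * t2a)
    D22 <- sum(b * t1b + d * t2b)
    Dy1 <- sum(a * t1q + cc * t2q)
    Dy2 <- sum(b * t1q + d * t2q)
    Dyy <- sum(q1 * t1q + q2 * t2q)
    logdetV <- sum(log(detM))
  }
  n <- ss$n; p <- ss$p
  G11 <- n - D11
  G12 <- ss$St_tot - D12
  G22 <- ss$Stt_tot - D22
  g1 <- ss$Sy_tot - Dy1
  g2 <- ss$Sty_tot - Dy2
  h <- ss$Syy - Dyy
  detG <- G11 * G22 - G12 * G12
  if (!is.finite(detG) || detG <= 0) {
    abort("Rank-deficient design: columns `(Intercept)` and `temperature` are collinear.")
  }
  beta1 <- (G22 * g1 - G12 * g2) / detG
  beta2 <- (G11 * g2 - G12 * g1) / detG
  r2 <- max(h - beta1 * g1 - beta2 * g2, 1e-300)
  crit <- if (is.null(sigma)) {
    if (estimator == "REML") {
      logdetV + log(detG) + (n - p) * (1 + log(2 * pi * r2 / (n - p)))
    } else {
      logdetV + n * (1 + log(2 * pi * r2 / n))
    }
  } else {
    s2 <- sigma * sigma
    if (estimator == "REML") {
      logdetV + log(detG) + (n - p) * log(2 * pi * s2) + r2 / s2
    } else {
      logdetV + n * log(2 * pi * s2) + r2 / s2
    }
  }
  if (!full) return(crit)
  Ginv <- matrix(c(G22, -G12, -G12, G11), 2, 2) / detG
  list(crit = crit, beta = c(`(Intercept)` = beta1, temperature = beta2),
       Ginv = Ginv, r2 = r2, logdetV = logdetV, detG = detG)
}

#' Profiled REML/ML criterion of a mixed model
#'
#' Evaluates the \eqn{-2} log restricted (or full) likelihood of the given
#' mixed-model structure at relative-Cholesky parameters `theta`, with the
#' fixed effects and the residual variance profiled out in closed form.
#'
#' @param data Data frame with columns `height`, `temperature`, `mountain`.
#' @param model Mixed-model id: `"M4"`, `"M5"`, `"M9"`, `"M10"` or `"M11"`.
#' @param theta Relative Cholesky parameters: length 1 for random-intercept
#'   models, 2 (intercept, slope) for independent intercept and slope, 3
#'   (`l11`, `l21`, `l22`, column-major lower triangle) for the correlated
#'   model.  Diagonal entries must be non-negative.
#' @param estimator `"REML"` (default) or `"ML"`.
#'
#' @return The criterion value (a single number; smaller is better).
#' @examples
#' d <- simulate_dataset(scenario_config("A", n_mountains = 4, seed = 1))
#' lmm_profiled_criterion(d, "M4", theta = 0.1)
#' @export
lmm_profiled_criterion <- function(data, model, theta,
                                   estimator = c("REML", "ML")) {
  estimator <- match.arg(estimator)
  struct <- lmm_structure(model)
  k <- n_theta(struct)
  if (length(theta) != k) {
    abort(sprintf("`theta` must have length %d for model %s.", k, model))
  }
  diag_idx <- if (struct == "corr") c(1L, 3L) else seq_len(k)
  if (any(theta[diag_idx] < 0)) {
    abort("Diagonal `theta` entries must be non-negative.")
  }
  lmm_eval(lmm_suffstats(data), theta, struct, estimator)
}

# Deterministic starting values: moment estimates from pooled OLS residuals
# (between-mountain mean spread, between-mountain OLS slope spread).
lmm_starts <- function(ss, structure) {
  n <- ss$n
  slope <- (ss$Sty_tot - ss$St_tot * ss$Sy_tot / n) /
    (ss$Stt_tot - ss$St_tot^2 / n)
  int <- (ss$Sy_tot - slope * ss$St_tot) / n
  ve <- max((ss$Syy + int^2 * n + slope^2 * ss$Stt_tot +
               2 * int * slope * ss$St_tot -
               2 * int * ss$Sy_tot - 2 * slope * ss$Sty_tot) / (n - 2), 1e-8)
  mbar <- (ss$Sy - int * ss$ni - slope * ss$St) / ss$ni
  v0 <- max(var(mbar) - ve * mean(1 / ss$ni), ve * 1e-4)
  th0 <- sqrt(v0 / ve)
  if (structure == "int") {
    starts <- list(th0, th0 / 4, pmin(4 * th0, 25), 1, 0.1)
  } else {
    sxx <- ss$Stt - ss$St^2 / ss$ni
    ok <- sxx > 1e-8
    bi <- rep(slope, ss$m)
    bi[ok] <- (ss$Sty[ok] - ss$St[ok] * ss$Sy[ok] / ss$ni[ok]) / sxx[ok]
    v1 <- max(var(bi) - ve * mean(1 / pmax(sxx, 1)), ve * 1e-4)
    th1 <- sqrt(v1 / ve)
    s <- c(th0, th1)
    if (structure == "diag") {
      starts <- list(s, s / 4, pmin(4 * s, 25), c(1, 1), c(0.1, 0.1))
    } else {
      w <- function(x) c(x[1], 0, x[2])
      starts <- list(w(s), w(s / 4), w(pmin(4 * s, 25)), c(1, 0, 1),
                     c(0.1, 0, 0.1))
    }
  }
  starts
}

#' Fit a linear mixed model by profiled REML or ML
#'
#' Minimizes the profiled criterion over the bounded relative-Cholesky
#' region (diagonal entries \eqn{\ge 0}).  Random-intercept models use
#' golden-section search on the single parameter with an explicit boundary
#' check at zero; two- and three-parameter structures use bounded
#' quasi-Newton (`L-BFGS-B`) from five deterministic starts (a moment-based
#' start, scaled versions of it, and two fixed fallbacks).  Boundary optima
#' are the singular fits flagged by [is_singular()].
#'
#' @inheritParams lmm_profiled_criterion
#'
#' @return An object of class `lmm_fit` with components `beta` (fixed
#'   effects), `beta_cov`, `theta`, `varcomp` (variance components on the
#'   data scale), `criterion`, `converged`, `singular`, and `ranef`
#'   (conditional means of the per-mountain deviations).  Use [tidy()] for
#'   Satterthwaite coefficient tests and [glance()] for a one-row summary.
#' @examples
#' d <- simulate_dataset(scenario_config("B", n_mountains = 6, seed = 3,
#'                                       var_slope = 0.25))
#' fit <- fit_lmm(d, "M10")
#' glance(fit)
#' tidy(fit)
#' @export
fit_lmm <- function(data, model = "M4", estimator = c("REML", "ML")) {
  estimator <- match.arg(estimator)
  struct <- lmm_structure(model)
  ss <- lmm_suffstats(data)
  obj <- function(th) lmm_eval(ss, th, struct, estimator)
  converged <- TRUE
  if (struct == "int") {
    opt <- optimize(obj, interval = c(0, 25), tol = 1e-9)
    cand <- rbind(c(opt$minimum, opt$objective), c(0, obj(0)))
    best <- cand[which.min(cand[, 2]), ]
    theta <- best[1]
    crit <- best[2]
    if (theta < 1e-6) theta <- 0
  } else {
    lower <- if (struct == "diag") c(0, 0) else c(0, -25, 0)
    upper <- rep(25, n_theta(struct))
    starts <- lmm_starts(ss, struct)
    f0 <- vapply(starts, obj, numeric(1))
    best <- NULL
    for (s in starts[order(f0)[1:2]]) {
      o <- tryCatch(
        optim(s, obj, method = "L-BFGS-B", lower = lower, upper = upper,
              control = list(factr = 1e7, maxit = 200)),
        error = function(e) NULL)
      if (is.null(o)) next
      if (is.null(best) || o$value < best$value) best <- o
    }
    if (is.null(best)) {
      abort("Mixed-model optimization failed from every start.")
    }
    theta <- best$par
    theta[abs(theta) < 1e-6] <- 0
    crit <- best$value
    converged <- best$convergence == 0
  }
  at <- lmm_eval(ss, theta, struct, estimator, full = TRUE)
  n <- ss$n; p <- ss$p
  sigma2 <- at$r2 / if (estimator == "REML") (n - p) else n
  beta_cov <- sigma2 * at$Ginv
  dimnames(beta_cov) <- list(names(at$beta), names(at$beta))
  vc <- theta_to_varcomp(theta, struct, sigma2)
  fit <- structure(
    list(model = model, structure = struct, estimator = estimator,
         beta = at$beta, beta_cov = beta_cov, theta = theta,
         varcomp = vc, sigma2_resid = sigma2, criterion = at$crit,
         converged = converged, n = n, m = ss$m, ss = ss),
    class = "lmm_fit")
  fit$singular <- is_singular(fit)
  fit$ranef <- lmm_ranef(ss, theta, struct, at$beta)
  fit
}

theta_to_varcomp <- function(theta, structure, sigma2) {
  if (structure == "int") {
    list(sigma2_intercept = sigma2 * theta[1]^2, sigma2_slope = 0,
         correlation = NA_real_)
  } else if (structure == "diag") {
    list(sigma2_intercept = sigma2 * theta[1]^2,
         sigma2_slope = sigma2 * theta[2]^2, correlation = NA_real_)
  } else {
    s2s <- theta[2]^2 + theta[3]^2
    list(sigma2_intercept = sigma2 * theta[1]^2,
         sigma2_slope = sigma2 * s2s,
         correlation = if (s2s > 0) theta[2] / sqrt(s2s) else NA_real_)
  }
}

# Conditional means (BLUPs) of the per-mountain deviations at theta-hat.
lmm_ranef <- function(ss, theta, structure, beta) {
  if (structure == "int") {
    l11 <- theta[1]
    Mi <- l11^2 * ss$ni + 1
    u <- l11 * (ss$Sy - ss$ni * beta[1] - ss$St * beta[2]) / Mi
    b0 <- l11 * u
    b1 <- rep(0, ss$m)
  } else {
    if (structure == "diag") {
      l11 <- theta[1]; l21 <- 0; l22 <- theta[2]
    } else {
      l11 <- theta[1]; l21 <- theta[2]; l22 <- theta[3]
    }
    a <- l11 * ss$ni + l21 * ss$St
    b <- l11 * ss$St + l21 * ss$Stt
    cc <- l22 * ss$St
    d <- l22 * ss$Stt
    M11 <- a * l11 + b * l21 + 1
    M12 <- b * l22
    M22 <- d * l22 + 1
    detM <- M11 * M22 - M12^2
    r1 <- (l11 * ss$Sy + l21 * ss$Sty) - a * beta[1] - b * beta[2]
    r2 <- l22 * ss$Sty - cc * beta[1] - d * beta[2]
    u1 <- (M22 * r1 - M12 * r2) / detM
    u2 <- (M11 * r2 - M12 * r1) / detM
    b0 <- l11 * u1
    b1 <- l21 * u1 + l22 * u2
  }
  tibble::tibble(mountain = factor(ss$levels, levels = ss$levels),
                 b_intercept = unname(b0), b_slope = unname(b1))
}

#' Detect a singular mixed-model fit
#'
#' A fit is singular when its variance-component estimate lies on the
#' boundary of the parameter space: a relative-Cholesky diagonal entry
#' (relative standard deviation) below `tol`, or, for the correlated
#' structure, an intercept-slope correlation within `tol` of \eqn{\pm 1}.
#'
#' @param fit An [fit_lmm()] result.
#' @param tol Boundary tolerance on the relative Cholesky scale.
#' @return `TRUE` or `FALSE`.
#' @export
is_singular <- function(fit, tol = 1e-4) {
  stopifnot(inherits(fit, "lmm_fit"))
  th <- fit$theta
  diag_idx <- if (fit$structure == "corr") c(1L, 3L) else seq_along(th)
  if (min(th[diag_idx]) < tol) return(TRUE)
  if (fit$structure == "corr") {
    s2s <- th[2]^2 + th[3]^2
    if (s2s > 0 && abs(th[2]) / sqrt(s2s) > 1 - tol) return(TRUE)
  }
  FALSE
}

#' Satterthwaite t-test for a population-level coefficient
#'
#' Approximates the denominator degrees of freedom of the t-statistic for one
#' fixed-effect coefficient by Satterthwaite moment matching:
#' \eqn{df = 2 v^2 / (g' A g)}, where \eqn{v} is the estimated coefficient
#' variance, \eqn{g} its gradient with respect to the variance parameters
#' \eqn{(\theta, \sigma)} at the optimum, and \eqn{A} twice the inverse
#' Hessian of the criterion in those parameters (the approximate covariance
#' of the variance-parameter estimates).  Derivatives use central finite
#' differences with step \eqn{10^{-4}(1 + |\eta_k|)}.  When the Hessian is
#' not positive definite (typical at boundary fits) the test falls back to
#' the residual degrees of freedom \eqn{n - p}; degrees of freedom are
#' floored at 1.
#'
#' @param fit An [fit_lmm()] result.
#' @param coefficient `"temperature"` (the slope) or `"(Intercept)"`.
#'
#' @return A one-row tibble: `coefficient`, `estimate`, `se`, `df`,
#'   `statistic`, `p.value`, `df_fallback` (logical; `TRUE` when the
#'   residual-df fallback was used).
#' @export
satterthwaite_test <- function(fit, coefficient = "temperature") {
  stopifnot(inherits(fit, "lmm_fit"))
  coefficient <- match.arg(coefficient, names(fit$beta))
  j <- match(coefficient, names(fit$beta))
  ss <- fit$ss
  n <- fit$n; p <- ss$p
  sigma <- sqrt(fit$sigma2_resid)
  eta <- c(fit$theta, sigma)
  k <- length(eta)
  fdev <- function(e) {
    lmm_eval(ss, e[-k], fit$structure, fit$estimator, sigma = e[k])
  }
  vfun <- function(e) {
    at <- lmm_eval(ss, e[-k], fit$structure, fit$estimator,
                   sigma = e[k], full = TRUE)
    e[k]^2 * at$Ginv[j, j]
  }
  hstep <- 1e-4 * (1 + abs(eta))
  hstep[k] <- min(hstep[k], sigma / 2)
  v <- sigma^2 * lmm_eval(ss, fit$theta, fit$structure, fit$estimator,
                          sigma = sigma, full = TRUE)$Ginv[j, j]
  se <- sqrt(v)
  est <- unname(fit$beta[j])
  tval <- est / se
  df <- NA_real_
  fallback <- FALSE
  H <- matrix(NA_real_, k, k)
  f0 <- fdev(eta)
  for (a in seq_len(k)) {
    ep <- eta; em <- eta
    ep[a] <- ep[a] + hstep[a]; em[a] <- em[a] - hstep[a]
    H[a, a] <- (fdev(ep) - 2 * f0 + fdev(em)) / hstep[a]^2
    if (a < k) {
      for (b in seq((a + 1), k)) {
        epp <- eta; epm <- eta; emp <- eta; emm <- eta
        epp[c(a, b)] <- epp[c(a, b)] + hstep[c(a, b)]
        emm[c(a, b)] <- emm[c(a, b)] - hstep[c(a, b)]
        epm[a] <- epm[a] + hstep[a]; epm[b] <- epm[b] - hstep[b]
        emp[a] <- emp[a] - hstep[a]; emp[b] <- emp[b] + hstep[b]
        H[a, b] <- H[b, a] <-
          (fdev(epp) - fdev(epm) - fdev(emp) + fdev(emm)) /
          (4 * hstep[a] * hstep[b])
      }
    }
  }
  A <- tryCatch(2 * chol2inv(chol(H)), error = function(e) NULL)
  if (!is.null(A)) {
    g <- vapply(seq_len(k), function(a) {
      ep <- eta; em <- eta
      ep[a] <- ep[a] + hstep[a]; em[a] <- em[a] - hstep[a]
      (vfun(ep) - vfun(em)) / (2 * hstep[a])
    }, numeric(1))
    denom <- drop(crossprod(g, A %*% g))
    if (is.finite(denom) && denom > 0) df <- 2 * v^2 / denom
  }
  if (!is.finite(df)) {
    df <- n - p
    fallback <- TRUE
  }
  df <- max(df, 1)
  tibble::tibble(
    coefficient = coefficient, estimate = est, se = se, df = df,
    statistic = tval, p.value = 2 * pt(-abs(tval), df),
    df_fallback = fallback)
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("<lmm_fit %s, %s> %d plants on %d mountains%s\n",
              x$model, x$estimator, x$n, x$m,
              if (x$singular) " [singular]" else ""))
  cat(sprintf("  fixed effects: intercept %.4f, slope %.4f cm\n",
              x$beta[1], x$beta[2]))
  cat(sprintf("  variances: intercept %.4g, slope %.4g, residual %.4g cm^2\n",
              x$varcomp$sigma2_intercept, x$varcomp$sigma2_slope,
              x$sigma2_resid))
  if (!is.na(x$varcomp$correlation)) {
    cat(sprintf("  intercept-slope correlation: %.3f\n",
                x$varcomp$correlation))
  }
  cat(sprintf("  %s criterion: %.4f\n", x$estimator, x$criterion))
  invisible(x)
}

#' @rdname fit_lmm
#' @param x An `lmm_fit` object.
#' @param ... Unused.
#' @export
tidy.lmm_fit <- function(x, ...) {
  dplyr::bind_rows(
    satterthwaite_test(x, "(Intercept)"),
    satterthwaite_test(x, "temperature"))
}

#' @rdname fit_lmm
#' @export
glance.lmm_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model, estimator = x$estimator, criterion = x$criterion,
    sigma2_resid = x$sigma2_resid,
    sigma2_intercept = x$varcomp$sigma2_intercept,
    sigma2_slope = x$varcomp$sigma2_slope,
    correlation = x$varcomp$correlation,
    singular = x$singular, converged = x$converged,
    nobs = x$n, n_mountains = x$m)
}
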