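# Independent oracles used across the suite. All are brute-force or
# closed-form computations that never touch the package's criterion code.

# Dense-matrix -2 log (restricted) likelihood: builds the marginal
# covariance V = I + Z L L' Z' explicitly per mountain and evaluates the
# profiled criterion by generalized least squares.
dense_criterion <- function(data, theta, structure, estimator = "REML") {
  y <- data$height
  t <- data$temperature
  g <- as.integer(data$mountain)
  n <- length(y)
  X <- cbind(1, t)
  if (structure == "int") {
    s11 <- theta[1]^2; s12 <- 0; s22 <- 0
  } else if (structure == "diag") {
    s11 <- theta[1]^2; s12 <- 0; s22 <- theta[2]^2
  } else {
    s11 <- theta[1]^2; s12 <- theta[1] * theta[2]
    s22 <- theta[2]^2 + theta[3]^2
  }
  V <- diag(n)
  for (i in unique(g)) {
    idx <- which(g == i)
    ti <- t[idx]
    ones <- rep(1, length(idx))
    V[idx, idx] <- V[idx, idx] + s11 * tcrossprod(ones) +
      s12 * (outer(ones, ti) + outer(ti, ones)) + s22 * tcrossprod(ti)
  }
  Vi <- solve(V)
  G <- t(X) %*% Vi %*% X
  beta <- solve(G, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  r2 <- drop(t(r) %*% Vi %*% r)
  p <- ncol(X)
  ld <- determinant(V, logarithm = TRUE)$modulus
  if (estimator == "REML") {
    ld + determinant(G, logarithm = TRUE)$modulus +
      (n - p) * (1 + log(2 * pi * r2 / (n - p)))
  } else {
    ld + n * (1 + log(2 * pi * r2 / n))
  }
}

# -2 log restricted likelihood of plain OLS height ~ temperature
# (the theta = 0 limit of the random-intercept criterion).
ols_restricted_criterion <- function(data, estimator = "REML") {
  fit <- lm(height ~ temperature, data = data)
  n <- nrow(data)
  rss <- sum(fit$residuals^2)
  X <- cbind(1, data$temperature)
  if (estimator == "REML") {
    determinant(crossprod(X), logarithm = TRUE)$modulus +
      (n - 2) * (1 + log(2 * pi * rss / (n - 2)))
  } else {
    n * (1 + log(2 * pi * rss / n))
  }
}

# Balanced random-intercept data with the temperature covariate centred
# within every mountain, so the classical one-way ANOVA algebra applies
# exactly on top of a within-mountain slope.
balanced_oneway_data <- function(m, n0, mu = 0.4, slope = 0.4,
                                 sd_b = 0.5, sd_e = 1, seed = 1) {
  withr::with_seed(seed, {
    t <- as.vector(vapply(seq_len(m), function(i) {
      x <- rnorm(n0)
      x - mean(x)
    }, numeric(n0)))
    b <- rnorm(m, 0, sd_b)
    g <- rep(seq_len(m), each = n0)
    y <- mu + b[g] + slope * t + rnorm(m * n0, 0, sd_e)
    tibble::tibble(height = y, temperature = t,
                   mountain = factor(g, levels = seq_len(m)))
  })
}

# Closed-form REML solution for balanced_oneway_data: the within mean
# square (after removing the within-mountain slope) and the one-way ANOVA
# moment estimator (MSB - MSW) / n0, valid whenever MSB > MSW.
balanced_oneway_oracle <- function(data) {
  g <- data$mountain
  m <- nlevels(g)
  n0 <- nrow(data) / m
  n <- nrow(data)
  ybar <- tapply(data$height, g, mean)
  yc <- data$height - ybar[g]
  tc <- data$temperature  # already centred within mountains
  ss_slope <- sum(yc * tc)^2 / sum(tc^2)
  ssw <- sum(yc^2) - ss_slope
  ssb <- n0 * sum((ybar - mean(data$height))^2)
  msw <- ssw / (n - m - 1)
  msb <- ssb / (m - 1)
  x <- msb / msw  # fitted theta^2 * n0 + 1 when >= 1
  r2 <- ssw * (n - 2) / (n - m - 1)
  crit <- m * log(x) + log(n / x) + log(sum(tc^2)) +
    (n - 2) * (1 + log(2 * pi * r2 / (n - 2)))
  list(sigma2_e = msw, sigma2_b = (msb - msw) / n0,
       anova_valid = msb > msw, criterion = crit)
}

# Minimal stand-in fit object for boundary classification checks.
fake_lmm_fit <- function(theta, structure) {
  structure(list(theta = theta, structure = structure), class = "lmm_fit")
}
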