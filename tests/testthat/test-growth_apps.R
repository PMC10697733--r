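# Synthetic growth fixtures -------------------------------------------------

# OD calibration curve: proportional at low cell number, saturating above.
make_calibration <- function(seed = 1, sigma = 0.01) {
  set.seed(seed)
  dil <- seq(0.02, 1, length.out = 25)
  od <- ifelse(dil <= 0.3, 2 * dil, 0.6 + 0.9 * (dil - 0.3) / (1 + 2 * (dil - 0.3)))
  y <- sapply(1:3, function(r) od + rnorm(25, 0, sigma))
  time_series(dil, y)
}

# Growth curve: lag, exponential at rate lambda, plateau (on OD scale).
make_growth_curve <- function(lambda = 0.8, seed = 1, sigma_log = 0.02) {
  set.seed(seed)
  t <- seq(0, 12, by = 0.2)
  logod <- ifelse(t < 2, log(0.05),
                  ifelse(t < 6, log(0.05) + lambda * (t - 2),
                         log(0.05) + lambda * 4))
  y <- sapply(1:3, function(r) exp(logod + rnorm(length(t), 0, sigma_log)))
  time_series(t, y)
}

test_that("od_linear_range finds the proportional region and scale factor", {
  ts <- make_calibration(seed = 71)
  res <- od_linear_range(ts, build_coefficient_prior(ts, y_range = c(0, 2)),
                         M_max = 4, quiet = TRUE)
  expect_gte(res$partition$M_best, 2L)
  lin <- res$linear_segment
  expect_equal(lin$start, 1L)
  # linear segment covers the small-dilution region, slope about 2
  expect_lt(ts$x[lin$end], 0.45)
  expect_gt(ts$x[lin$end], 0.2)
  expect_equal(res$scale_factor, res$od_max / res$dilution_at_od_max)
  expect_equal(res$scale_factor, 2, tolerance = 0.1)
})

test_that("exactly proportional data give one segment and its slope", {
  set.seed(72)
  x <- seq(0.05, 1, length.out = 15)
  ts <- time_series(x, sapply(1:2, function(r) 2 * x + rnorm(15, 0, 0.005)))
  res <- od_linear_range(ts, build_coefficient_prior(ts, y_range = c(0, 2.5)),
                         M_max = 3, quiet = TRUE)
  expect_equal(res$partition$M_best, 1L)
  expect_equal(res$scale_factor, 2, tolerance = 0.05)
})

test_that("find_log_phase selects the exponential segment", {
  ts <- make_growth_curve(lambda = 0.8, seed = 73)
  res <- find_log_phase(
    ts, function(lts) build_coefficient_prior(lts, gradient_range = c(0, 5)),
    M_max = 5, quiet = TRUE)
  expect_gte(res$partition$M_best, 3L)
  expect_equal(res$specific_growth_rate, 0.8, tolerance = 0.05)
  # the selected segment sits in the exponential window (t in [2, 6])
  expect_gt(ts$x[res$log_phase$end], 4)
  expect_lt(ts$x[res$log_phase$start], 4)
})

test_that("log-phase rate is invariant to rescaling OD", {
  ts <- make_growth_curve(lambda = 0.6, seed = 74)
  pr <- function(lts) build_coefficient_prior(lts, gradient_range = c(0, 5))
  r1 <- find_log_phase(ts, pr, M_max = 4, quiet = TRUE)
  ts2 <- time_series(ts$x, ts$y * 3.7)
  r2 <- find_log_phase(ts2, pr, M_max = 4, quiet = TRUE)
  expect_equal(r1$specific_growth_rate, r2$specific_growth_rate,
               tolerance = 1e-6)
})

test_that("non-positive OD is rejected with the offending rows", {
  y <- c(0.1, -0.2, 0.3, 0.4, 0.5, 0.6)
  ts <- time_series(1:6, y)
  expect_error(find_log_phase(ts, wide_prior()), "positive.*2")
})

test_that("a single-slope curve returns one segment with that slope", {
  set.seed(75)
  t <- seq(0, 5, by = 0.25)
  ts <- time_series(t, sapply(1:3, function(r)
    exp(log(0.05) + 0.5 * t + rnorm(length(t), 0, 0.01))))
  res <- find_log_phase(
    ts, function(lts) build_coefficient_prior(lts, gradient_range = c(0, 5)),
    M_max = 3, quiet = TRUE)
  expect_equal(res$partition$M_best, 1L)
  expect_equal(res$specific_growth_rate, 0.5, tolerance = 0.02)
})

# Monod ---------------------------------------------------------------------

monod_data <- function(lambda_max = 0.4, K_M = 0.03, sigma = 0.01, seed = 1) {
  set.seed(seed)
  s <- rep(2 * 2^-(0:18), 2)               # two technical replicates
  lam <- lambda_max * s / (K_M + s) + rnorm(length(s), 0, sigma)
  data.frame(s = s, lambda = lam)
}

test_that("monod_loglik matches definition and the sigma-integral oracle", {
  d <- monod_data(seed = 81)
  # half-rate at s = K_M; saturation at large s (model identities via loglik)
  expect_equal(0.4 * 0.03 / (0.03 + 0.03), 0.2)
  ll <- monod_loglik(0.4, 0.03, d)
  expect_equal(ll, -(nrow(d) / 2) * log(sum((d$lambda - 0.4 * d$s / (0.03 + d$s))^2)))
  # oracle: numerically integrate the Gaussian likelihood times 1/sigma
  num_marginal <- function(lmax, km) {
    r2 <- sum((d$lambda - lmax * d$s / (km + d$s))^2)
    N <- nrow(d)
    # integral over sigma of sigma^(-N) * exp(-r2 / 2 sigma^2) * (1/sigma),
    # in u = log sigma for stability
    g <- function(u) exp(-N * u - r2 / (2 * exp(2 * u)))
    integrate(g, log(1e-4), log(10), rel.tol = 1e-10)$value
  }
  lhs <- monod_loglik(0.4, 0.03, d) - monod_loglik(0.35, 0.05, d)
  rhs <- log(num_marginal(0.4, 0.03)) - log(num_marginal(0.35, 0.05))
  expect_equal(lhs, rhs, tolerance = 1e-4)
})

test_that("monod_loglik is homogeneous under rate rescaling", {
  d <- monod_data(seed = 82)
  for (c in c(2, 10)) {
    d2 <- data.frame(s = d$s, lambda = c * d$lambda)
    expect_equal(monod_loglik(c * 0.4, 0.03, d2),
                 monod_loglik(0.4, 0.03, d) - nrow(d) * log(c),
                 tolerance = 1e-10)
  }
})

test_that("fit_monod recovers parameters within two standard errors", {
  for (seed in 83:85) {
    d <- monod_data(seed = seed)
    fit <- fit_monod(d)
    expect_lt(abs(fit$lambda_max - 0.4), 2.5 * fit$err_lambda_max + 0.02)
    expect_lt(abs(fit$K_M - 0.03), 2.5 * fit$err_K_M + 0.01)
    expect_true(fit$lambda_max > 0 && fit$K_M > 0)
  }
  # noiseless data: exact recovery to optimizer tolerance
  s <- 2 * 2^-(0:18)
  d0 <- data.frame(s = s, lambda = 0.4 * s / (0.03 + s) + 1e-9)
  fit0 <- fit_monod(d0)
  expect_equal(fit0$lambda_max, 0.4, tolerance = 1e-4)
  expect_equal(fit0$K_M, 0.03, tolerance = 1e-3)
})

test_that("fit_monod validates its inputs", {
  expect_error(fit_monod(data.frame(s = c(1, 2), lambda = c(1, 2))), "3 data")
  expect_error(fit_monod(data.frame(s = rep(1, 5), lambda = rnorm(5))),
               "distinct")
})
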