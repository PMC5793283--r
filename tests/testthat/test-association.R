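test_that("first-stage OLS matches the closed-form least-squares expressions", {
  set.seed(21)
  x <- rpois(60, 6); y <- 50 + 2.5 * x + rnorm(60, 0, 20)
  f <- fit_linear(y, x)

  slope_hat <- cov(x, y) / var(x)
  resid <- y - mean(y) - slope_hat * (x - mean(x))
  s2 <- sum(resid^2) / (60 - 2)
  se_hat <- sqrt(s2 / (59 * var(x)))
  r2_hat <- slope_hat^2 * var(x) / var(y)

  expect_equal(f$slope, slope_hat, tolerance = 1e-10)
  expect_equal(f$slope_se, se_hat, tolerance = 1e-10)
  expect_equal(f$intercept, mean(y) - slope_hat * mean(x), tolerance = 1e-10)
  expect_equal(f$r2, r2_hat, tolerance = 1e-10)
  # F / R2 identity holds on every fit
  expect_equal(f$f_stat, f$r2 * (f$n - 2) / (1 - f$r2), tolerance = 1e-12)
})

test_that("perfect linearity, F arithmetic, and degenerate inputs", {
  x <- 1:20; y <- 3 + 2 * x
  f <- suppressWarnings(fit_linear(y, x))
  expect_equal(f$r2, 1, tolerance = 1e-12)
  expect_equal(f$slope, 2, tolerance = 1e-10)
  expect_lt(f$slope_se, 1e-8)

  # the instrument-strength arithmetic: R2 = 2.6%, n = 1782 gives F ~ 47.5
  expect_equal(f_from_r2(0.026, 1782), 47.5154, tolerance = 1e-4)
  expect_identical(round(f_from_r2(0.026, 1782)), 48)

  expect_error(fit_linear(rnorm(10), rep(1, 10)), "zero variance")

  # listwise deletion is logged; adjusted slope reported separately
  y2 <- c(y, NA); x2 <- c(x, 5)
  f2 <- suppressWarnings(fit_linear(y2, x2, covariates = cbind(z = rnorm(21))))
  expect_identical(f2$n_dropped, 1L)
  expect_true(!is.null(f2$slope_adj))
})

test_that("Cox coefficient matches brute-force partial-likelihood maximisation", {
  for (seed in c(1, 2, 3)) {
    d <- make_tiny_survival(6, seed = seed)
    f <- fit_cox(d$time, d$event, d$x)
    oracle <- oracle_cox_mle(d$time, d$event, d$x)
    expect_equal(f$coef, oracle, tolerance = 1e-6)
    # the oracle likelihood evaluated at the fit equals the fit's loglik
    expect_equal(f$loglik, oracle_cox_loglik(f$coef, d$time, d$event, d$x),
                 tolerance = 1e-8)
  }
})

test_that("score test at beta = 0 equals the logrank chi-square (tie-free, binary)", {
  set.seed(33)
  n <- 80
  group <- rep(0:1, each = n / 2)
  time <- rexp(n, 0.1 * exp(0.5 * group))
  event <- as.integer(time < quantile(time, 0.8))
  time <- pmin(time, quantile(time, 0.8) + seq_len(n) * 1e-9)  # keep distinct
  f <- fit_cox(time, event, group)
  sc <- summary(f$fit)$sctest[["test"]]
  expect_equal(sc, oracle_logrank(time, event, group), tolerance = 1e-8)
})

test_that("covariate rescaling scales the coefficient and preserves the loglik", {
  set.seed(8)
  n <- 150
  x <- rnorm(n)
  time <- rexp(n, 0.2 * exp(0.4 * x))
  event <- as.integer(time < 5); time <- pmin(time, 5)
  f1 <- fit_cox(time, event, x)
  f2 <- fit_cox(time, event, x * 10)
  expect_equal(f2$coef, f1$coef / 10, tolerance = 1e-8)
  expect_equal(f2$loglik, f1$loglik, tolerance = 1e-10)
})

test_that("Breslow reduces to the plain partial likelihood without ties", {
  set.seed(13)
  n <- 60
  x <- rnorm(n)
  time <- rexp(n, 0.3 * exp(0.3 * x)) + seq_len(n) * 1e-8
  event <- rbinom(n, 1, 0.7)
  fb <- fit_cox(time, event, x, ties = "breslow")
  fe <- fit_cox(time, event, x, ties = "efron")
  expect_equal(fb$coef, fe$coef, tolerance = 1e-10)
  expect_equal(fb$loglik, fe$loglik, tolerance = 1e-10)
})

test_that("known log-hazard effects are recovered without bias at scale", {
  set.seed(55)
  gamma <- 0.35
  n <- 5000; nrep <- 30
  est <- se <- numeric(nrep)
  for (r in seq_len(nrep)) {
    x <- rnorm(n)
    t <- rexp(n, 0.05 * exp(gamma * x))
    ev <- as.integer(t <= 10); t <- pmin(t, 10)
    f <- fit_cox(t, ev, x)
    est[r] <- f$coef; se[r] <- f$coef_se
  }
  expect_lt(abs(mean(est) - gamma), 3 * sd(est) / sqrt(nrep))
})

test_that("zero events error; monotone likelihood is flagged, not hidden", {
  expect_error(fit_cox(c(1, 2, 3), c(0, 0, 0), c(1, 2, 3)), "no events")
  # a covariate that perfectly separates events produces a divergent coef
  time <- c(1, 2, 3, 4, 5, 6)
  event <- c(1, 1, 1, 0, 0, 0)
  x <- c(1, 1, 1, 0, 0, 0)
  expect_warning(f <- fit_cox(time, event, x), "non-converged")
  expect_false(f$converged)
})

test_that("proportionality diagnostics behave under the null and detect violations", {
  # Schoenfeld residuals sum to zero at the fitted coefficient
  set.seed(61)
  n <- 100; x <- rnorm(n)
  t <- rexp(n, 0.2 * exp(0.3 * x)); ev <- as.integer(t < 4); t <- pmin(t, 4)
  f <- fit_cox(t, ev, x)
  expect_lt(abs(sum(residuals(f$fit, type = "schoenfeld"))), 1e-6)

  # null calibration: p-values roughly uniform under exact PH
  set.seed(62)
  pvals <- replicate(60, {
    x <- rnorm(150)
    t <- rexp(150, 0.2 * exp(0.4 * x))
    ev <- as.integer(t < 5); t <- pmin(t, 5)
    check_proportionality(fit_cox(t, ev, x))[["exposure"]]
  })
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)

  # power: an effect reversing sign mid-follow-up is detected at large n
  set.seed(63)
  n <- 4000
  g <- rep(0:1, each = n / 2)
  t0 <- 1
  # piecewise-exponential: group 1 hazard 0.8 before t0, 0.1 after; group 0 flat 0.3
  h1a <- 0.8; h1b <- 0.1; h0 <- 0.3
  u <- runif(n)
  t <- ifelse(g == 0, -log(u) / h0,
              ifelse(-log(u) / h1a <= t0, -log(u) / h1a,
                     t0 + (-log(u) - h1a * t0) / h1b))
  ev <- as.integer(t < 6); t <- pmin(t, 6)
  p_violate <- check_proportionality(fit_cox(t, ev, g))[["exposure"]]
  expect_lt(p_violate, 0.001)

  # too few events: undefined, reported as missing
  f3 <- fit_cox(c(1, 2, 3, 4), c(1, 1, 0, 0), c(0.5, -0.2, 0.1, 0.3))
  expect_true(all(is.na(check_proportionality(f3))))
})

test_that("incidence rates per 1000 person-years are computed and bounded", {
  expect_equal(rate_table("a", 10, 50, 1000)$rate_per_1000, 10)
  expect_equal(rate_table("b", 0, 50, 1000)$rate_per_1000, 0)
  # reference row back-solved from a printed rate: 1091 cases, 112,358 pyrs
  expect_equal(round(rate_table("ref", 1091, 6468, 112358)$rate_per_1000, 2),
               9.71)
  expect_error(rate_table("a", -1, 10, 100), "non-negative")
  expect_error(rate_table("a", 5, 10, 0), "positive")
  expect_error(rate_table("a", 11, 10, 100), "exceed")
})
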