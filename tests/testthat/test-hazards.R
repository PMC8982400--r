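test_that("divergence hazard matches the truncated-normal definition", {
  d <- div_dist(0.005, 0.005)
  # frozen from a high-precision pdf / survival evaluation
  expect_equal(div_hazard(0.005, d), 159.57691216057307, tolerance = 1e-10)
  # direct pdf/survival at arbitrary points
  tt <- c(0, 0.002, 0.0071, 0.02)
  expect_equal(div_hazard(tt, d),
               dnorm(tt, 0.005, 0.005) / pnorm(tt, 0.005, 0.005,
                                               lower.tail = FALSE),
               tolerance = 1e-12)
  # increasing on [0, tau_mean] for several parameter sets
  for (tm in c(0.001, 0.01, 0.05)) {
    for (sd in c(tm / 10, tm, 3 * tm)) {
      grid <- seq(0, tm, length.out = 50)
      expect_true(all(diff(div_hazard(grid, div_dist(tm, sd))) > 0))
    }
  }
  # enormous spread: hazard nearly constant over [0, 0.01]
  dflat <- div_dist(0.005, 0.005 * 1e4)
  h <- div_hazard(c(0, 0.01), dflat)
  expect_lt(abs(h[2] / h[1] - 1), 0.01)
  # domain errors
  db <- div_dist(0.005, 0.001, b1 = 0.01)
  expect_error(div_hazard(0.01, db), "support")
  expect_error(div_hazard(-0.001, d), "support")
})

test_that("cumulative hazard: closed form, additivity, quadrature", {
  d <- div_dist(0.005, 0.005)
  expect_identical(div_cum_hazard(0.003, 0, d), 0)
  # frozen quadrature value for the reference setting
  expect_equal(div_cum_hazard(0, 0.005, d), 0.5203934015364954,
               tolerance = 1e-10)
  set.seed(1)
  for (i in 1:20) {
    a <- runif(1, 0, 0.01); b <- runif(1, 0, 0.01); t0 <- runif(1, 0, 0.01)
    expect_equal(div_cum_hazard(t0, a + b, d),
                 div_cum_hazard(t0, a, d) + div_cum_hazard(t0 + a, b, d),
                 tolerance = 1e-10)
  }
  # closed form vs quadrature over a log-spaced parameter grid
  worst <- 0
  for (tm in 10^seq(-3, -1.5, length.out = 4)) {
    for (sd in tm * c(0.1, 1)) {
      for (b1 in c(Inf, 4 * tm)) {
        dd <- div_dist(tm, sd, b1)
        t0 <- tm / 3; u <- tm / 2
        q <- integrate(function(x) div_hazard(x, dd), t0, t0 + u,
                       rel.tol = 1e-12)$value
        worst <- max(worst, abs(div_cum_hazard(t0, u, dd) - q) /
                       max(q, 1e-12))
      }
    }
  }
  expect_lt(worst, 1e-8)
  expect_error(div_cum_hazard(0, 0.02, div_dist(0.005, 0.001, b1 = 0.01)))
})

test_that("waiting density is proper and consistent with the hazard", {
  d <- div_dist(0.004, 0.002)
  t0 <- 0.001
  tot <- integrate(function(u) div_waiting_density(t0, u, d), 0, 0.03,
                   rel.tol = 1e-9)$value
  expect_equal(tot, 1, tolerance = 1e-6)
  expect_equal(div_waiting_density(t0, 0, d), div_hazard(t0, d),
               tolerance = 1e-12)
  # bounded support: still proper
  db <- div_dist(0.004, 0.002, b1 = 0.008)
  totb <- integrate(function(u) div_waiting_density(t0, u, db), 0,
                    0.008 - t0, rel.tol = 1e-9)$value
  expect_equal(totb, 1, tolerance = 1e-6)
  # sd -> 0: mass concentrates at tau_mean - t0
  dn <- div_dist(0.004, 1e-5)
  mass <- integrate(function(u) div_waiting_density(0.001, u, dn),
                    0.003 - 5e-5, 0.003 + 5e-5, rel.tol = 1e-8)$value
  expect_gt(mass, 0.999)
})

test_that("inverse-transform divergence draws invert the survival function", {
  d <- div_dist(0.005, 0.002)
  set.seed(42)
  t0 <- runif(1e4, 0, 0.0049)
  r <- runif(1e4)
  u <- sample_div_time(t0, r, d)
  expect_lt(max(abs(exp(-div_cum_hazard(t0, u, d)) - (1 - r))), 1e-8)
  # degenerate limit
  dn <- div_dist(0.005, 1e-7)
  expect_equal(sample_div_time(0.001, 0.5, dn), 0.004, tolerance = 1e-5)
  # distribution of draws matches the analytic cdf at t0 = 0
  set.seed(7)
  x <- sample_div_time(rep(0, 2e4), runif(2e4), d)
  cdf <- function(q) 1 - exp(-div_cum_hazard(rep(0, length(q)), q, d))
  ks <- suppressWarnings(stats::ks.test(x, cdf))
  expect_gt(ks$p.value, 0.01)
  # bounded draws respect b1 and r = 1 hits the bound
  db <- div_dist(0.005, 0.002, b1 = 0.02)
  expect_equal(sample_div_time(0.001, 1, db), 0.019, tolerance = 1e-9)
  expect_error(sample_div_time(0.001, 0, d), "\\(0, 1\\]")
})

test_that("exact first-event probabilities behave as competing risks", {
  d <- div_dist(0.005, 0.005)
  # frozen quadrature value at the reference competing rate
  expect_equal(xi_divergence_exact(400, d), 0.1885734173450602,
               tolerance = 1e-6)
  # nothing competes: divergence always first
  expect_equal(xi_divergence_exact(0, d), 1, tolerance = 1e-8)
  # partition of unity
  set.seed(3)
  for (i in 1:10) {
    dd <- div_dist(10^runif(1, -3, -1.5), 10^runif(1, -3.5, -1.5))
    lc <- 10^runif(1, 0, 3); lm <- 10^runif(1, 0, 3)
    tot <- xi_constant_exact(lc, lc + lm, dd) +
      xi_constant_exact(lm, lc + lm, dd) +
      xi_divergence_exact(lc + lm, dd)
    expect_equal(tot, 1, tolerance = 1e-6)
  }
  # monotone in both rates
  x1 <- xi_divergence_exact(100, d)
  x2 <- xi_divergence_exact(300, d)
  expect_gt(x1, x2)
})

test_that("midpoint approximation is the simple rate ratio", {
  expect_equal(xi_divergence_approx(100, 100), 0.5)
  expect_equal(xi_divergence_approx(300, 100), 0.25)
  expect_error(xi_divergence_approx(0, 0), "zero")
  # algebraic partition of unity
  lc <- 120; lm <- 40; ld <- 77
  expect_identical(lc / (lc + lm + ld) + lm / (lc + lm + ld) +
                     xi_divergence_approx(lc + lm, ld), 1)
  # monotonicity mirrors the exact version
  d <- div_dist(0.005, 0.005)
  expect_gt(xi_divergence_approx_at(100, d), xi_divergence_approx_at(300, d))
})

test_that("tail evaluation does not overflow far beyond the mean", {
  d <- div_dist(0.005, 0.0005)
  t8 <- 0.005 + 8 * 0.0005
  expect_true(is.finite(div_hazard(t8, d)))
  expect_true(is.finite(div_cum_hazard(0, t8, d)))
  expect_gt(div_cum_hazard(0, t8, d), 10)
  u <- sample_div_time(t8, 0.5, d)
  expect_true(is.finite(u) && u > 0)
})
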