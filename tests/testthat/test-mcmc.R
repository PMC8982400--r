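test_that("prior specifications sample and evaluate consistently", {
  m <- two_pop_model()
  pr <- prior_spec(m,
    theta = list(dist = "uniform", min = 0.001, max = 0.05),
    tau_mean = list(dist = "exponential", mean = 0.01, upper = 0.03),
    tau_sd = list(dist = "uniform", min = 1e-5, max = 0.005))
  expect_setequal(names(pr$priors),
                  c("theta_anc", "theta_der", "tau_mean_der", "tau_sd_der"))
  pe <- pr$priors$tau_mean_der
  set.seed(30)
  x <- coaldiv:::prior_draw(pe, 5000)
  expect_true(all(x > 0 & x <= 0.03))
  ks <- suppressWarnings(
    stats::ks.test(x, function(q) pexp(q, 100) / pexp(0.03, 100)))
  expect_gt(ks$p.value, 0.01)
  # density is normalized on the truncated support
  tot <- integrate(function(q) exp(coaldiv:::prior_logdens(q, pe)), 0,
                   0.03)$value
  expect_equal(tot, 1, tolerance = 1e-6)
  expect_identical(coaldiv:::prior_logdens(0.05, pe), -Inf)
})

test_that("posterior kernel is additive over loci and respects support", {
  m <- two_pop_model(2, 2)
  p <- param_set(m, theta = 0.01, tau_mean = 0.004, tau_sd = 0.001,
                 b1 = 0.09)
  pr <- prior_spec(m,
    theta = list(dist = "uniform", min = 0.001, max = 0.05),
    tau_mean = list(dist = "exponential", mean = 0.01, upper = 0.03),
    tau_sd = list(dist = "uniform", min = 1e-5, max = 0.005))
  dat1 <- simulate_dataset(m, p, loci = 1, sites = 120, seed = 31)
  g <- dat1$genealogies[[1]]
  k1 <- log_posterior_kernel(list(g), p, dat1, m, pr)
  # doubled data with identical loci doubles the data-dependent part
  dat2 <- dat1
  dat2$alignments <- rep(dat1$alignments, 2)
  k2 <- log_posterior_kernel(list(g, g), p, dat2, m, pr)
  vsum <- sum(vapply(names(pr$priors), function(nm)
    coaldiv:::prior_logdens(coaldiv:::param_vector(p, m)[[nm]],
                            pr$priors[[nm]]), 1))
  expect_equal(k2 - vsum, 2 * (k1 - vsum), tolerance = 1e-9)
  # outside the prior support the kernel is -Inf
  p_out <- param_set(m, theta = 0.2, tau_mean = 0.004, tau_sd = 0.001,
                     b1 = 0.09)
  expect_identical(log_posterior_kernel(list(g), p_out, dat1, m, pr), -Inf)
})

test_that("lineage re-simulation proposals keep genealogies valid", {
  m <- three_pop_model(2, 2)
  p <- param_set(m, theta = c(0.01, 0.02, 0.015), mig = c(40, 40),
                 tau_mean = c(0.004, 0.005), tau_sd = c(0.002, 0.002))
  set.seed(32)
  g <- simulate_genealogy(m, p)
  for (i in 1:300) {
    pr <- propose_genealogy(g, p, m)
    if (!isTRUE(pr$ok)) next
    expect_identical(validate_genealogy(pr$g, m), character(0))
    expect_true(is.finite(pr$log_hastings))
    if (i %% 3 == 0) g <- pr$g   # walk around the state space
  }
})

test_that("proposal density is consistent between draw and replay", {
  m <- two_pop_model(2, 2)
  p <- param_set(m, theta = 0.0255, tau_mean = 0.0084, tau_sd = 0.0026,
                 b1 = 0.09)
  set.seed(33)
  for (rep in 1:150) {
    g <- simulate_genealogy(m, p)
    cand <- setdiff(seq_along(g$parent), which(g$parent == 0))
    cn <- sample(cand, 1)
    det <- coaldiv:::detach_lineage(g, cn)
    sim <- coaldiv:::path_process(g, det, p, m, mode = "simulate")
    if (!isTRUE(sim$ok)) next
    g2 <- coaldiv:::reassemble_genealogy(g, det, sim)
    expect_identical(validate_genealogy(g2, m), character(0))
    det2 <- coaldiv:::detach_lineage(g2, cn)
    rev2 <- coaldiv:::path_process(g2, det2, p, m, mode = "evaluate")
    expect_equal(rev2$logq, sim$logq, tolerance = 1e-9)
    # detaching the old path and re-attaching it reproduces the genealogy
    fake <- list(ok = TRUE, path_ev = det$path_ev, ext_ev = det$ext_ev,
                 attach = det$attach)
    gb <- coaldiv:::reassemble_genealogy(g, det, fake)
    expect_equal(genealogy_log_density(gb, p, m),
                 genealogy_log_density(g, p, m), tolerance = 1e-9)
  }
})

test_that("fixed-parameter genealogy chain reproduces the simulator's law", {
  m <- two_pop_model(1, 1)
  p <- param_set(m, theta = 0.02, tau_mean = 0.008, tau_sd = 0.002,
                 b1 = 0.09)
  set.seed(34)
  g <- simulate_genealogy(m, p)
  nit <- 6000
  Tt <- numeric(nit)
  for (i in seq_len(nit)) {
    prp <- propose_genealogy(g, p, m)
    if (isTRUE(prp$ok)) {
      dl <- genealogy_log_density(prp$g, p, m) -
        genealogy_log_density(g, p, m) + prp$log_hastings
      if (is.finite(dl) && log(runif(1)) < dl) g <- prp$g
    }
    Tt[i] <- g$events$time[1]
  }
  # switch time of the derived tip has cdf 1 - exp(-Lambda)
  d <- div_dist(0.008, 0.002, 0.09)
  cdf <- function(q) 1 - exp(-div_cum_hazard(rep(0, length(q)), q, d))
  ks <- suppressWarnings(stats::ks.test(Tt[seq(1000, nit, 25)], cdf))
  expect_gt(ks$p.value, 0.01)
})

test_that("prior-only chains recover the prior marginals", {
  m <- two_pop_model(2, 2)
  pr <- prior_spec(m,
    theta = list(dist = "uniform", min = 0.001, max = 0.05),
    tau_mean = list(dist = "exponential", mean = 0.01, upper = 0.03),
    tau_sd = list(dist = "uniform", min = 1e-4, max = 0.005))
  fit <- run_chain(NULL, m, pr,
                   chain_config(iterations = 6000, burnin = 1000,
                                thin = 4, seed = 35, genealogy_updates = 3))
  s <- fit$summary
  te <- integrate(function(x) x * dexp(x, 100) / pexp(0.03, 100), 0,
                  0.03)$value
  tol <- function(sdv, ess) 4 * sdv / sqrt(max(ess, 10))
  th <- s[s$parameter == "theta_anc", ]
  expect_lt(abs(th$mean - 0.0255), tol(0.049 / sqrt(12), th$ess))
  tm <- s[s$parameter == "tau_mean_der", ]
  expect_lt(abs(tm$mean - te), tol(0.0077, tm$ess))
  ts <- s[s$parameter == "tau_sd_der", ]
  expect_lt(abs(ts$mean - 0.00255), tol(0.0049 / sqrt(12), ts$ess))
})

test_that("posterior summaries follow the histogram-mode convention", {
  set.seed(36)
  sam <- data.frame(a = rep(2.5, 200), b = runif(5000),
                    c = rexp(5000))
  s <- summarize_posterior(sam, bins = 200)
  sa <- s[s$parameter == "a", ]
  expect_true(sa$degenerate)
  expect_equal(sa$mode, 2.5)
  expect_equal(sa$std_width, 0)
  sb <- s[s$parameter == "b", ]
  expect_lt(abs(sb$p2.5 - 0.025), 0.01)
  expect_lt(abs(sb$p97.5 - 0.975), 0.01)
  sc <- s[s$parameter == "c", ]
  expect_lt(abs(sc$p97.5 - qexp(0.975)), 0.3)
  expect_lt(abs(sc$p2.5 - qexp(0.025)), 0.01)
  expect_error(summarize_posterior(data.frame(a = 1:10)), "100")
})

test_that("fit objects expose broom-style summaries and plots", {
  m <- two_pop_model(2, 2)
  pr <- prior_spec(m,
    theta = list(dist = "uniform", min = 0.001, max = 0.05),
    tau_mean = list(dist = "exponential", mean = 0.01, upper = 0.03),
    tau_sd = list(dist = "uniform", min = 1e-4, max = 0.005))
  fit <- run_chain(NULL, m, pr,
                   chain_config(iterations = 600, burnin = 100, thin = 1,
                                seed = 37))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("parameter", "mode", "std_width") %in% names(td)))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$seed, 37)
  pl <- ggplot2::autoplot(fit)
  expect_s3_class(pl, "ggplot")
})
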