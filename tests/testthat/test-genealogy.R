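test_that("interval rates follow the structured-coalescent formulas", {
  expect_equal(coalescent_rate(2, 0.02), 100)
  expect_equal(coalescent_rate(1, 0.02), 0)
  expect_equal(coalescent_rate(5, 0.01), 2000)
  expect_error(coalescent_rate(2, 0), "theta")

  m <- two_pop_model(migration = TRUE)
  p <- param_set(m, theta = 0.01, mig = c(50, 10), tau_mean = 0.005,
                 tau_sd = 0.001)
  # M_anc->der = 50 acts on der lineages, M_der->anc = 10 on anc lineages
  expect_equal(migration_total_rate(c(1, 2), p, m), 2 * 50 + 1 * 10)
  expect_equal(migration_total_rate(c(0, 0), p, m), 0)
  m0 <- pop_model(c("x", "y"), c(1, 1))
  p0 <- param_set(m0, theta = 0.01)
  expect_equal(migration_total_rate(c(1, 1), p0, m0), 0)
})

test_that("interval log density combines survival and the event factor", {
  m1 <- pop_model("A", 2)
  p1 <- param_set(m1, theta = 0.02)
  # k = 2, coalescence after u = 0.01: exponential density 100 e^-1
  ld <- interval_log_density(0, 0.01, 2, list(kind = "coalescence", i = 1),
                             p1, m1)
  expect_equal(ld, log(100 * exp(-1)), tolerance = 1e-12)
  # migration with rate zero is impossible
  mm <- two_pop_model(migration = TRUE)
  pm <- param_set(mm, theta = 0.02, mig = 0, tau_mean = 0.005,
                  tau_sd = 0.001)
  expect_identical(
    interval_log_density(0, 0.01, c(1, 1),
                         list(kind = "migration", i = 2, j = 1), pm, mm),
    -Inf)
  # two derived lineages, interval [0, 0.005] ending in one divergence:
  # oracle assembled from quadrature-validated pieces
  m2 <- two_pop_model()
  p2 <- param_set(m2, theta = 0.01, mig = numeric(0), tau_mean = 0.005,
                  tau_sd = 0.005)
  mig <- two_pop_model(migration = TRUE)
  pmig <- param_set(mig, theta = 0.01, mig = 100, tau_mean = 0.005,
                    tau_sd = 0.005)
  d <- div_dist(0.005, 0.005)
  lam_cm <- 2 * (2 - 1) / 0.01 + 2 * 100
  Lam <- integrate(function(x) div_hazard(x, d), 0, 0.005,
                   rel.tol = 1e-12)$value
  oracle <- -0.005 * lam_cm - 2 * Lam + log(div_hazard(0.005, d))
  got <- interval_log_density(0, 0.005, c(0, 2),
                              list(kind = "divergence", i = 2, j = 1),
                              pmig, mig)
  expect_equal(got, oracle, tolerance = 1e-8)
})

test_that("genealogy density matches Kingman closed forms", {
  m1 <- pop_model("A", 2)
  p1 <- param_set(m1, theta = 0.02)
  g2 <- event_genealogy(c("A_1", "A_2"), c(1L, 1L), c(3L, 3L, 0L),
                        c(0, 0, 0.01), c(1L, 1L, 1L), model = m1)
  expect_equal(genealogy_log_density(g2, p1, m1), log(100 * exp(-1)),
               tolerance = 1e-12)

  m3 <- pop_model("A", 3)
  p3 <- param_set(m3, theta = 0.02)
  t1 <- 0.002; t2 <- 0.009
  g3 <- event_genealogy(paste0("A_", 1:3), rep(1L, 3),
                        c(4L, 4L, 5L, 5L, 0L), c(0, 0, 0, t1, t2),
                        rep(1L, 5), model = m3)
  closed <- log(2 / 0.02) - (6 / 0.02) * t1 +
    log(2 / 0.02) - (2 / 0.02) * (t2 - t1)
  expect_equal(genealogy_log_density(g3, p3, m3), closed,
               tolerance = 1e-12)
})

test_that("pair genealogy density equals the analytic closed form", {
  m <- two_pop_model(1, 1)
  for (b1 in c(Inf, 0.09)) {
    p <- param_set(m, theta = 0.02, tau_mean = 0.008, tau_sd = 0.002,
                   b1 = b1)
    d <- div_dist(0.008, 0.002, b1)
    for (tc in list(c(0.004, 0.01), c(0.008, 0.009), c(0.012, 0.05))) {
      g <- pair_genealogy(tc[1], tc[2], m)
      closed <- log(div_hazard(tc[1], d)) - div_cum_hazard(0, tc[1], d) +
        log(2 / 0.02) - (2 / 0.02) * (tc[2] - tc[1])
      expect_equal(genealogy_log_density(g, p, m), closed,
                   tolerance = 1e-10)
    }
  }
})

test_that("density of event-rich genealogies matches the brute-force oracle", {
  m <- three_pop_model(3, 3)
  p <- param_set(m, theta = c(0.01, 0.02, 0.015), mig = c(30, 60),
                 tau_mean = c(0.004, 0.006), tau_sd = c(0.002, 0.002))
  set.seed(11)
  n_checked <- 0
  for (i in 1:15) {
    g <- simulate_genealogy(m, p)
    if (nrow(g$events) < 3) next
    n_checked <- n_checked + 1
    expect_equal(genealogy_log_density(g, p, m),
                 brute_force_log_density(g, p, m), tolerance = 1e-7)
  }
  expect_gt(n_checked, 5)
})

test_that("two-tip density integrates to one over the coalescence time", {
  m1 <- pop_model("A", 2)
  p1 <- param_set(m1, theta = 0.02)
  f <- function(t) vapply(t, function(tt) {
    g <- event_genealogy(c("A_1", "A_2"), c(1L, 1L), c(3L, 3L, 0L),
                         c(0, 0, tt), c(1L, 1L, 1L))
    exp(genealogy_log_density(g, p1, m1))
  }, 1)
  tot <- integrate(f, 0, 1, rel.tol = 1e-9)$value
  expect_equal(tot, 1, tolerance = 1e-6)
})

test_that("genealogy validation reports label and containment violations", {
  m <- two_pop_model(1, 1)
  # divergence event missing: derived tip coalesces while still labeled der
  g_bad <- event_genealogy(
    c("anc_1", "der_1"), c(1L, 2L), c(3L, 3L, 0L), c(0, 0, 0.01),
    c(1L, 2L, 1L))
  v <- validate_genealogy(g_bad, m)
  expect_true(any(grepl("joins labels", v)))
  # event outside its branch
  g2 <- pair_genealogy(0.004, 0.01, m)
  g2$events$time <- 0.02
  expect_true(any(grepl("outside branch", validate_genealogy(g2, m))))
  # reversed divergence direction
  g3 <- pair_genealogy(0.004, 0.01, m)
  g3$events$from <- 1L; g3$events$to <- 2L
  expect_gt(length(validate_genealogy(g3, m)), 0)
})

test_that("conversion to ape phylo preserves times and topology", {
  m <- two_pop_model(3, 3)
  p <- param_set(m, theta = 0.01, tau_mean = 0.003, tau_sd = 0.001)
  set.seed(5)
  g <- simulate_genealogy(m, p)
  ph <- ape::as.phylo(g)
  expect_s3_class(ph, "phylo")
  expect_true(ape::is.ultrametric(ph, tol = 1e-10))
  expect_setequal(ph$tip.label, g$tip_labels)
  depth <- max(ape::node.depth.edgelength(ph))
  expect_equal(depth, max(g$node_time), tolerance = 1e-12)
})
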