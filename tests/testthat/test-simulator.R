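test_that("single-population simulation reproduces Kingman moments", {
  m <- pop_model("A", 20)
  p <- param_set(m, theta = 0.02)
  set.seed(100)
  reps <- 600
  tm <- replicate(reps, max(simulate_genealogy(m, p)$node_time))
  # E[TMRCA] = Theta (1 - 1/n) in mutation units
  expected <- 0.02 * (1 - 1 / 20)
  se <- sd(tm) / sqrt(reps)
  expect_lt(abs(mean(tm) - expected), 4 * se)
})

test_that("degenerate divergence: no migration, all switches at the epoch", {
  m <- two_pop_model(5, 5, migration = TRUE)
  p <- param_set(m, theta = 0.01, mig = 0, tau_mean = 0.005,
                 tau_sd = 1e-8)
  set.seed(101)
  g <- simulate_genealogy(m, p)
  ev <- g$events
  expect_true(all(ev$kind == "divergence"))
  expect_true(all(abs(ev$time - 0.005) < 1e-6))
  # epoch mode with a fixed epoch gives a hard split exactly there
  g2 <- simulate_genealogy(m, p, mode = "epoch", epoch_times = 0.004)
  ev2 <- g2$events[g2$events$kind == "divergence", ]
  expect_true(all(ev2$time == 0.004))
})

test_that("first-event frequencies match the exact xi probabilities", {
  # two derived lineages competing: coalescence vs divergence (no migration)
  m <- two_pop_model(0, 2)
  p <- param_set(m, theta = 0.01, tau_mean = 0.004, tau_sd = 0.004)
  d <- div_dist(0.004, 0.004)
  lam_c <- coalescent_rate(2, 0.01)
  xi_c <- xi_constant_exact(lam_c, lam_c, d, n_risk = 2)
  xi_d <- xi_divergence_exact(lam_c, d, n_risk = 2)
  expect_equal(xi_c + xi_d, 1, tolerance = 1e-6)
  set.seed(102)
  reps <- 1500
  first_is_div <- replicate(reps, {
    g <- simulate_genealogy(m, p)
    hap_t <- c(g$node_time[-(1:2)], g$events$time)
    kinds <- c(rep("c", length(g$node_time) - 2), g$events$kind)
    kinds[which.min(hap_t)] == "divergence"
  })
  ph <- prop.test(sum(first_is_div), reps, p = xi_d)$p.value
  expect_gt(ph, 0.001)
})

test_that("simulated genealogies always satisfy the structural invariants", {
  set.seed(103)
  for (i in 1:12) {
    nA <- sample(2:4, 1); nB <- sample(1:4, 1)
    m <- three_pop_model(nA, nB)
    p <- param_set(m, theta = runif(3, 0.005, 0.03),
                   mig = runif(2, 0, 100),
                   tau_mean = runif(2, 0.002, 0.01),
                   tau_sd = runif(2, 5e-4, 5e-3))
    g <- simulate_genealogy(m, p)
    expect_identical(validate_genealogy(g, m), character(0))
    expect_true(is.finite(genealogy_log_density(g, p, m)))
  }
})

test_that("epoch draws are zero-truncated normal with exact degenerate case", {
  expect_identical(as.numeric(draw_divergence_epoch(0.005, 0)), 0.005)
  set.seed(104)
  x <- draw_divergence_epoch(0.002, 0.002, n = 4000)
  expect_true(all(x > 0))
  # rejection of the left tail pushes the accepted mean above the mean
  expect_gt(mean(x), 0.002)
  raw <- attr(x, "raw")
  expect_gte(length(raw), length(x))
})

test_that("sequence simulation follows the F84 process", {
  m <- two_pop_model(1, 1)
  p <- param_set(m, theta = 0.02, tau_mean = 0.005, tau_sd = 0.001)
  # zero branch lengths: all sequences equal the root draw
  g0 <- event_genealogy(c("anc_1", "der_1"), c(1L, 2L), c(3L, 3L, 0L),
                        c(0, 0, 0), c(1L, 1L, 1L))
  set.seed(105)
  a0 <- simulate_sequences(g0, 300)
  expect_identical(a0[1, ], a0[2, ])
  # very long branches: tip composition approaches stationarity
  mut <- mutation_model(freqs = c(0.4, 0.3, 0.2, 0.1))
  gL <- event_genealogy(c("anc_1", "der_1"), c(1L, 2L), c(3L, 3L, 0L),
                        c(0, 0, 50), c(1L, 1L, 1L))
  aL <- simulate_sequences(gL, 20000, mut)
  fr <- table(factor(aL[1, ], levels = c("a", "c", "g", "t"))) / 20000
  expect_lt(max(abs(as.numeric(fr) - mut$freqs)), 0.02)
  # pairwise mismatch on a two-tip tree matches the transition matrix
  tt <- 0.05
  gP <- event_genealogy(c("anc_1", "der_1"), c(1L, 2L), c(3L, 3L, 0L),
                        c(0, 0, tt / 2), c(1L, 1L, 1L))
  P2 <- f84_transition_matrix(tt, mut)
  p_diff <- 1 - sum(mut$freqs * diag(P2))
  nrep <- 40000
  aP <- simulate_sequences(gP, nrep, mut)
  obs <- mean(aP[1, ] != aP[2, ])
  expect_lt(abs(obs - p_diff), 4 * sqrt(p_diff * (1 - p_diff) / nrep))
})

test_that("multi-locus datasets are reproducible per locus", {
  m <- two_pop_model(3, 3)
  p <- param_set(m, theta = 0.01, tau_mean = 0.003, tau_sd = 0.001)
  d1 <- simulate_dataset(m, p, loci = 3, sites = 100, seed = 9)
  d2 <- simulate_dataset(m, p, loci = 3, sites = 100, seed = 9)
  expect_identical(d1$alignments, d2$alignments)
  expect_false(identical(d1$alignments[[1]], d1$alignments[[2]]))
})

test_that("lineage survival declines from one to zero across split times", {
  m <- island_model(10, 10)
  p <- param_set(m, theta = 0.01, mig = 100)
  sv <- lineage_survival_fraction(m, p, tau_grid = c(1e-6, 0.01, 0.3),
                                  reps = 150, seed = 12)
  expect_equal(sv$frac_surviving[1], 1)
  expect_lt(sv$frac_surviving[3], 0.05)
  expect_true(all(diff(sv$frac_surviving) <= 0))
})
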