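test_that("F84 transition matrices are valid and reach stationarity", {
  mut <- mutation_model(freqs = c(0.35, 0.15, 0.3, 0.2), ts_tv = 3)
  P0 <- f84_transition_matrix(0, mut)
  expect_equal(P0, diag(4), tolerance = 1e-12)
  Pinf <- f84_transition_matrix(200, mut)
  for (i in 1:4) expect_equal(unname(Pinf[i, ]), mut$freqs,
                              tolerance = 1e-9)
  for (t in c(0.01, 0.3, 2)) {
    P <- f84_transition_matrix(t, mut)
    expect_equal(rowSums(P), rep(1, 4), tolerance = 1e-12)
    expect_true(all(P >= 0))
    # detailed balance (reversibility)
    F <- diag(mut$freqs) %*% P
    expect_equal(F, t(F), tolerance = 1e-10)
  }
  # the expected ts/tv ratio at stationarity is the requested one
  t <- 1e-6
  P <- f84_transition_matrix(t, mut)
  fl <- diag(mut$freqs) %*% P
  ts <- fl[1, 3] + fl[3, 1] + fl[2, 4] + fl[4, 2]
  tv <- sum(fl) - sum(diag(fl)) - ts
  expect_equal(ts / tv, 3, tolerance = 1e-3)
  expect_error(f84_transition_matrix(-1, mut), ">= 0")
  expect_error(mutation_model(freqs = c(0.5, 0.5, 0.2, 0.2)), "summing to 1")
})

test_that("equal-frequency F84 equals the Kimura two-parameter closed form", {
  mut <- mutation_model(ts_tv = 2)   # equal frequencies
  a <- mut$Q[1, 3]   # transition rate
  b <- mut$Q[1, 2]   # each transversion rate
  for (t in c(0.02, 0.1, 0.5, 1.5)) {
    P <- f84_transition_matrix(t, mut)
    p_same <- 0.25 + 0.25 * exp(-4 * b * t) + 0.5 * exp(-2 * (a + b) * t)
    p_ts <- 0.25 + 0.25 * exp(-4 * b * t) - 0.5 * exp(-2 * (a + b) * t)
    p_tv <- 0.25 - 0.25 * exp(-4 * b * t)
    expect_equal(P[1, 1], p_same, tolerance = 1e-10)
    expect_equal(P[1, 3], p_ts, tolerance = 1e-10)
    expect_equal(P[1, 2], p_tv, tolerance = 1e-10)
  }
})

test_that("pruning matches direct site probabilities on tiny trees", {
  m <- two_pop_model(1, 1)
  mut <- mutation_model(freqs = c(0.4, 0.3, 0.2, 0.1))
  # identical one-site sequences at coalescence time ~ 0
  g0 <- event_genealogy(c("anc_1", "der_1"), c(1L, 2L), c(3L, 3L, 0L),
                        c(0, 0, 1e-12), c(1L, 1L, 1L))
  for (base in 1:4) {
    aln <- matrix(c("a", "c", "g", "t")[base], 2, 1,
                  dimnames = list(c("anc_1", "der_1"), NULL))
    expect_equal(pruning_loglike(g0, aln, mut), log(mut$freqs[base]),
                 tolerance = 1e-6)
  }
  # label-switch events never change the likelihood
  mmig <- two_pop_model(1, 1, migration = TRUE)
  gev <- pair_genealogy(0.004, 0.01, mmig)
  gno <- gev; gno$events <- gno$events[0, ]
  set.seed(21)
  aln <- simulate_sequences(gev, 200, mut)
  expect_identical(pruning_loglike(gev, aln, mut),
                   pruning_loglike(gno, aln, mut))
})

test_that("pruning equals exhaustive ancestral-state enumeration", {
  mut <- mutation_model(freqs = c(0.3, 0.2, 0.25, 0.25), ts_tv = 2.5)
  m <- pop_model("A", 3)
  t1 <- 0.03; t2 <- 0.11
  g <- event_genealogy(paste0("A_", 1:3), rep(1L, 3),
                       c(4L, 4L, 5L, 5L, 0L), c(0, 0, 0, t1, t2),
                       rep(1L, 5))
  set.seed(22)
  aln <- simulate_sequences(g, 10, mut)
  # brute force: sum over the 16 assignments of the two internal nodes
  P_t1 <- f84_transition_matrix(t1, mut)
  P_rt <- f84_transition_matrix(t2, mut)          # root -> tip 3
  P_ri <- f84_transition_matrix(t2 - t1, mut)     # root -> inner node
  codes <- match(aln, c("a", "c", "g", "t"))
  dim(codes) <- dim(aln)
  brute <- 0
  for (s in seq_len(ncol(aln))) {
    x <- codes[, s]
    tot <- 0
    for (anc in 1:4) for (inn in 1:4) {
      tot <- tot + mut$freqs[anc] * P_rt[anc, x[3]] * P_ri[anc, inn] *
        P_t1[inn, x[1]] * P_t1[inn, x[2]]
    }
    brute <- brute + log(tot)
  }
  expect_equal(pruning_loglike(g, aln, mut), brute, tolerance = 1e-10)
  # ambiguity: an N row contributes a marginal sum, never an error
  aln[1, 1] <- "n"
  expect_true(is.finite(pruning_loglike(g, aln, mut)))
})

test_that("site likelihoods sum to one over all tip patterns", {
  mut <- mutation_model(freqs = c(0.4, 0.1, 0.3, 0.2))
  g <- event_genealogy(paste0("A_", 1:3), rep(1L, 3),
                       c(4L, 4L, 5L, 5L, 0L), c(0, 0, 0, 0.05, 0.2),
                       rep(1L, 5))
  bases <- c("a", "c", "g", "t")
  tot <- 0
  for (i in 1:4) for (j in 1:4) for (k in 1:4) {
    aln <- matrix(c(bases[i], bases[j], bases[k]), 3, 1,
                  dimnames = list(paste0("A_", 1:3), NULL))
    tot <- tot + exp(pruning_loglike(g, aln, mut))
  }
  expect_equal(tot, 1, tolerance = 1e-9)
})
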