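# Shared fixture builders. All models are small; anything larger is
# generated inside the test that needs it.

# population 2 splits from population 1; population 1 is ancestral and
# present-day; optional symmetric migration
two_pop_model <- function(n1 = 2, n2 = 2, migration = FALSE) {
  pop_model(c("anc", "der"), c(n1, n2),
            mig_edges = if (migration) rbind(c(1, 2), c(2, 1)),
            div_edges = rbind(c(2, 1)))
}

# two contemporary populations splitting from an unsampled ancestor,
# with migration among the contemporary pair
three_pop_model <- function(nA = 2, nB = 2) {
  pop_model(c("A", "B", "C"), c(nA, nB, 0),
            mig_edges = rbind(c(1, 2), c(2, 1)),
            div_edges = rbind(c(1, 3), c(2, 3)))
}

island_model <- function(n1 = 20, n2 = 20) {
  pop_model(c("A", "B"), c(n1, n2),
            mig_edges = rbind(c(1, 2), c(2, 1)))
}

# hand-built genealogy: 1 ancestral tip + 1 derived tip, switch at T,
# coalescence at C
pair_genealogy <- function(T, C, model) {
  event_genealogy(
    tip_labels = c("anc_1", "der_1"), tip_pop = c(1L, 2L),
    parent = c(3L, 3L, 0L), node_time = c(0, 0, C),
    node_pop = c(1L, 2L, 1L),
    events = data.frame(node = 2L, time = T, kind = "divergence",
                        from = 2L, to = 1L),
    model = model)
}

# independent per-interval density evaluation used as an oracle against
# genealogy_log_density(): walks the event list chronologically and
# multiplies survival and event factors term by term, with the cumulative
# divergence hazard obtained by numerical integration of div_hazard()
brute_force_log_density <- function(g, params, model) {
  np <- model$n_pop
  hap <- rbind(
    data.frame(time = g$node_time[-seq_len(g$n_tips)], kind = "coalescence",
               i = g$node_pop[-seq_len(g$n_tips)], j = NA),
    if (nrow(g$events)) data.frame(time = g$events$time, kind = g$events$kind,
                                   i = g$events$from, j = g$events$to))
  hap <- hap[order(hap$time), ]
  k <- tabulate(g$tip_pop, np)
  t0 <- 0
  ll <- 0
  inc <- numeric(np)
  if (nrow(model$mig_edges)) {
    for (r in seq_len(nrow(model$mig_edges))) {
      inc[model$mig_edges[r, 2]] <- inc[model$mig_edges[r, 2]] +
        params$mig[r]
    }
  }
  for (r in seq_len(nrow(hap))) {
    u <- hap$time[r] - t0
    lam <- sum(k * (k - 1) / params$theta) + sum(k * inc)
    ll <- ll - u * lam
    for (e in seq_len(nrow(model$div_edges))) {
      kd <- k[model$div_edges[e, 1]]
      if (kd > 0 && u > 0) {
        d <- div_dist(params$tau_mean[e], params$tau_sd[e], params$b1[e])
        ll <- ll - kd * integrate(function(x) div_hazard(x, d), t0,
                                  hap$time[r], rel.tol = 1e-10)$value
      }
    }
    if (hap$kind[r] == "coalescence") {
      ll <- ll + log(2 / params$theta[hap$i[r]])
      k[hap$i[r]] <- k[hap$i[r]] - 1
    } else {
      if (hap$kind[r] == "migration") {
        w <- which(model$mig_edges[, 1] == hap$j[r] &
                   model$mig_edges[, 2] == hap$i[r])
        ll <- ll + log(params$mig[w])
      } else {
        w <- which(model$div_edges[, 1] == hap$i[r] &
                   model$div_edges[, 2] == hap$j[r])
        d <- div_dist(params$tau_mean[w], params$tau_sd[w], params$b1[w])
        ll <- ll + log(div_hazard(hap$time[r], d))
      }
      k[hap$i[r]] <- k[hap$i[r]] - 1
      k[hap$j[r]] <- k[hap$j[r]] + 1
    }
    t0 <- hap$time[r]
  }
  unname(ll)
}
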