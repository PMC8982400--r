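# Backward-in-time simulation under coalescence + migration + divergence
# label switching, following the competing-draws scheme: at each step a
# waiting time is proposed for every possible event class (exponential for
# coalescence and migration, survival inversion of the truncated-normal
# hazard for divergence) and the earliest one is applied.

#' Simulate an event-augmented genealogy
#'
#' Runs the backward-in-time structured coalescent with migration and
#' lineage label switching until the sample reaches its most recent common
#' ancestor. Two divergence modes are available: `"hazard"` draws an
#' independent truncated-normal switching time for each at-risk lineage
#' (the inference model); `"epoch"` draws one zero-truncated normal epoch
#' per divergence edge and switches every derived lineage at that shared
#' time (a hard split at a random time, the classical simulation
#' convention), after which migration edges touching the derived
#' population are shut off.
#'
#' @param model a [pop_model()].
#' @param params a [param_set()].
#' @param mode divergence simulation mode, `"hazard"` (default) or
#'   `"epoch"`.
#' @param locus locus identifier stored on the genealogy.
#' @param epoch_times optional pre-drawn epoch times (one per divergence
#'   edge) for `mode = "epoch"`; drawn with [draw_divergence_epoch()]
#'   when missing.
#' @param max_events safety cap on label-switch events; exceeding it is an
#'   error reporting the runaway configuration.
#' @return an [event_genealogy()].
#' @examples
#' m <- pop_model(c("anc", "der"), c(3, 3), div_edges = rbind(c(2, 1)))
#' p <- param_set(m, theta = 0.01, tau_mean = 0.005, tau_sd = 0.0005)
#' set.seed(1)
#' g <- simulate_genealogy(m, p)
#' @export
simulate_genealogy <- function(model, params, mode = c("hazard", "epoch"),
                               locus = 1L, epoch_times = NULL,
                               max_events = NULL) {
  mode <- match.arg(mode)
  n <- sum(model$sample_counts)
  stopifnot(n >= 2)
  if (is.null(max_events)) max_events <- 1000L * n
  np <- model$n_pop
  nd <- nrow(model$div_edges)
  if (mode == "epoch" && nd > 0 && is.null(epoch_times)) {
    epoch_times <- vapply(seq_len(nd), function(e)
      draw_divergence_epoch(params$tau_mean[e], params$tau_sd[e], 1), 1)
  }

  tip_pop <- rep(seq_len(np), model$sample_counts)
  tip_labels <- unlist(lapply(seq_len(np), function(i)
    sprintf("%s_%d", model$labels[i], seq_len(model$sample_counts[i]))),
    use.names = FALSE)

  m <- 2L * n - 1L
  parent <- integer(m)
  node_time <- numeric(m)
  node_pop <- integer(m)
  node_pop[seq_len(n)] <- tip_pop
  ev_node <- integer(0); ev_time <- numeric(0); ev_kind <- character(0)
  ev_from <- integer(0); ev_to <- integer(0)

  active_id <- seq_len(n)
  active_lab <- tip_pop
  next_node <- n + 1L
  t <- 0
  inc <- incoming_mig_rate(model, params)
  mig_active <- rep(TRUE, nrow(model$mig_edges))
  n_events <- 0L

  while (length(active_id) > 1L) {
    k <- tabulate(active_lab, np)
    # competing proposals
    best_t <- Inf; best <- NULL
    for (i in seq_len(np)) {
      if (k[i] >= 2L) {
        tc <- t + rexp(1, coalescent_rate(k[i], params$theta[i]))
        if (tc < best_t) { best_t <- tc; best <- list(kind = "c", i = i) }
      }
    }
    if (any(mig_active)) {
      inc_now <- incoming_mig_rate(
        model, list(mig = ifelse(mig_active, params$mig, 0)))
      for (i in seq_len(np)) {
        ri <- k[i] * inc_now[i]
        if (ri > 0) {
          tm <- t + rexp(1, ri)
          if (tm < best_t) { best_t <- tm; best <- list(kind = "m", i = i) }
        }
      }
    }
    if (nd > 0) {
      for (e in seq_len(nd)) {
        dpop <- model$div_edges[e, 1]
        if (k[dpop] == 0L) next
        if (mode == "hazard") {
          if (t >= params$b1[e]) next
          td <- t + .sampdiv(t, runif(1), params$tau_mean[e],
                             params$tau_sd[e], params$b1[e],
                             n_risk = k[dpop])
        } else {
          td <- if (epoch_times[e] > t) epoch_times[e] else Inf
        }
        if (td < best_t) { best_t <- td; best <- list(kind = "d", e = e) }
      }
    }
    if (is.null(best) || !is.finite(best_t)) {
      stop("simulation cannot proceed: no event is possible for ",
           "the current lineage configuration (labels ",
           paste(model$labels[unique(active_lab)], collapse = ", "), ")")
    }
    t <- best_t
    if (best$kind == "c") {
      i <- best$i
      pick <- sample(which(active_lab == i), 2L)
      v <- next_node; next_node <- next_node + 1L
      parent[active_id[pick]] <- v
      node_time[v] <- t
      node_pop[v] <- i
      active_id <- c(active_id[-pick], v)
      active_lab <- c(active_lab[-pick], i)
    } else if (best$kind == "m") {
      i <- best$i
      el <- which(model$mig_edges[, 2] == i & mig_active & params$mig > 0)
      j <- model$mig_edges[sample(rep(el, 2), 1, prob = rep(params$mig[el], 2)), 1]
      w <- sample(rep(which(active_lab == i), 2), 1)
      ev_node <- c(ev_node, active_id[w]); ev_time <- c(ev_time, t)
      ev_kind <- c(ev_kind, "migration")
      ev_from <- c(ev_from, i); ev_to <- c(ev_to, j)
      active_lab[w] <- j
      n_events <- n_events + 1L
    } else {
      e <- best$e
      dpop <- model$div_edges[e, 1]; apop <- model$div_edges[e, 2]
      who <- which(active_lab == dpop)
      if (mode == "epoch") {
        # every derived lineage switches at the shared epoch; stagger the
        # recorded times infinitesimally so branch event lists stay ordered
        for (w in who) {
          ev_node <- c(ev_node, active_id[w]); ev_time <- c(ev_time, t)
          ev_kind <- c(ev_kind, "divergence")
          ev_from <- c(ev_from, dpop); ev_to <- c(ev_to, apop)
          active_lab[w] <- apop
          n_events <- n_events + 1L
        }
        mig_active[model$mig_edges[, 1] == dpop |
                   model$mig_edges[, 2] == dpop] <- FALSE
      } else {
        w <- sample(rep(who, 2), 1)
        ev_node <- c(ev_node, active_id[w]); ev_time <- c(ev_time, t)
        ev_kind <- c(ev_kind, "divergence")
        ev_from <- c(ev_from, dpop); ev_to <- c(ev_to, apop)
        active_lab[w] <- apop
        n_events <- n_events + 1L
      }
    }
    if (n_events > max_events) {
      stop("more than ", max_events, " label-switch events: runaway ",
           "configuration (check migration rates and divergence edges)")
    }
  }
  events <- data.frame(node = ev_node, time = ev_time, kind = ev_kind,
                       from = ev_from, to = ev_to)
  new_event_genealogy(n, tip_labels, tip_pop, parent, node_time, node_pop,
                      events, locus)
}

#' Draw a shared divergence epoch
#'
#' One zero-truncated normal draw: a normal variate with the given mean and
#' standard deviation, redrawn while non-positive. With `tau_sd = 0` the
#' mean is returned exactly. The raw (pre-rejection) draws are attached as
#' attribute `"raw"`; with a large spread a sizable fraction of raw draws
#' is rejected, which skews the accepted epochs old.
#'
#' @param tau_mean mean of the underlying normal (> 0).
#' @param tau_sd standard deviation (`>= 0`).
#' @param n number of epochs to draw.
#' @return numeric vector of `n` positive epoch times, attribute `"raw"`
#'   holding all underlying normal draws.
#' @export
draw_divergence_epoch <- function(tau_mean, tau_sd, n = 1) {
  stopifnot(tau_mean > 0, tau_sd >= 0, n >= 1)
  if (tau_sd == 0) {
    return(structure(rep(tau_mean, n), raw = rep(tau_mean, n)))
  }
  out <- numeric(0)
  raw <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(max(n - length(out), 16L), tau_mean, tau_sd)
    raw <- c(raw, x)
    out <- c(out, x[x > 0])
  }
  structure(out[seq_len(n)], raw = raw)
}

#' Simulate sequences along a genealogy under the F84 model
#'
#' Root states are drawn from the stationary base frequencies and evolved
#' down every branch with the F84 transition probabilities. Migration and
#' divergence events do not touch the substitution process.
#'
#' @param g an [event_genealogy()].
#' @param sites number of sites.
#' @param mut a [mutation_model()].
#' @return character matrix (tips x sites) of bases, rownames = tip labels.
#' @export
simulate_sequences <- function(g, sites, mut = mutation_model()) {
  stopifnot(inherits(g, "event_genealogy"), sites >= 1)
  m <- 2L * g$n_tips - 1L
  r <- root_node(g)
  states <- matrix(NA_integer_, m, sites)
  states[r, ] <- sample.int(4L, sites, replace = TRUE, prob = mut$freqs)
  # process nodes parent-before-child
  ord <- order(g$node_time[setdiff(seq_len(m), r)], decreasing = TRUE)
  for (v in setdiff(seq_len(m), r)[ord]) {
    p <- g$parent[v]
    P <- f84_transition_matrix(g$node_time[p] - g$node_time[v], mut)
    sv <- integer(sites)
    for (s in 1:4) {
      idx <- which(states[p, ] == s)
      if (length(idx)) sv[idx] <- sample.int(4L, length(idx),
                                             replace = TRUE, prob = P[s, ])
    }
    states[v, ] <- sv
  }
  out <- matrix(c("a", "c", "g", "t")[states[seq_len(g$n_tips), ]],
                g$n_tips, sites)
  rownames(out) <- g$tip_labels
  out
}

#' Simulate a multi-locus dataset
#'
#' Independent genealogies and alignments per locus under one population
#' model and parameter set. Each locus gets its own deterministic RNG
#' stream derived from `seed`, so loci are reproducible individually.
#'
#' @inheritParams simulate_genealogy
#' @param loci number of loci.
#' @param sites sites per locus.
#' @param mut a [mutation_model()].
#' @param seed integer seed.
#' @return an object of class `coaldiv_data`: list with `model`,
#'   `alignments` (per-locus character matrices), `genealogies`
#'   (per-locus [event_genealogy()]), `tip_pop`, and the call settings.
#' @export
simulate_dataset <- function(model, params, loci = 1L, sites = 1000L,
                             mut = mutation_model(),
                             mode = c("hazard", "epoch"), seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(loci >= 1, sites >= 1)
  gs <- vector("list", loci)
  als <- vector("list", loci)
  for (l in seq_len(loci)) {
    set.seed((as.integer(seed) + 48271L * l) %% .Machine$integer.max)
    gs[[l]] <- simulate_genealogy(model, params, mode = mode, locus = l)
    als[[l]] <- simulate_sequences(gs[[l]], sites, mut)
  }
  structure(list(model = model, alignments = als, genealogies = gs,
                 tip_pop = gs[[1]]$tip_pop, tip_labels = gs[[1]]$tip_labels,
                 sites = sites, mut = mut, seed = seed, mode = mode,
                 true_params = params),
            class = "coaldiv_data")
}

#' @export
print.coaldiv_data <- function(x, ...) {
  cat(sprintf("coaldiv dataset: %d locus/loci, %d tips, %d sites each\n",
              length(x$alignments), length(x$tip_labels), x$sites))
  invisible(x)
}

# Count-level backward simulation: only per-population lineage counts are
# tracked (no tree), which is all the lineage-survival experiment needs.
# Returns the coalescence times of one replicate, in increasing order.
sim_coalescence_times <- function(model, params, stop_time = Inf) {
  np <- model$n_pop
  k <- tabulate(rep(seq_len(np), model$sample_counts), np)
  inc <- incoming_mig_rate(model, params)
  t <- 0
  out <- numeric(sum(k) - 1L)
  nc <- 0L
  while (sum(k) > 1L && t < stop_time) {
    rc <- coalescent_rate(k, params$theta)
    rm <- k * inc
    tot <- sum(rc) + sum(rm)
    if (tot <= 0) break   # isolated lineages: no further coalescence
    t <- t + rexp(1, tot)
    if (t >= stop_time) break
    pick <- sample.int(2L * np, 1L, prob = c(rc, rm))
    if (pick <= np) {
      k[pick] <- k[pick] - 1L
      nc <- nc + 1L
      out[nc] <- t
    } else {
      i <- pick - np
      el <- which(model$mig_edges[, 2] == i & params$mig > 0)
      j <- model$mig_edges[sample(rep(el, 2), 1,
                                  prob = rep(params$mig[el], 2)), 1]
      k[i] <- k[i] - 1L
      k[j] <- k[j] + 1L
    }
  }
  out[seq_len(nc)]
}

#' Fraction of replicates with surviving lineages at candidate split times
#'
#' Simulates the below-split dynamics of the isolation-with-migration
#' model (structured coalescent with migration among the sampled
#' populations) and reports, for each candidate split time `tau`, the
#' fraction of replicates in which two or more sampled lineages remain
#' uncoalesced at `tau`. Once a sample has coalesced into a single lineage
#' before the split, the data carry no information about the split time.
#' Because the dynamics below the split do not depend on where the split
#' is placed, one set of replicates yields the whole curve.
#'
#' @param model a [pop_model()] (migration edges only are used).
#' @param params a [param_set()].
#' @param tau_grid candidate split times, mutation-scaled.
#' @param reps number of simulated replicates.
#' @param seed integer seed.
#' @return a tibble with columns `tau`, `frac_surviving`, `reps`.
#' @examples
#' m <- pop_model(c("A", "B"), c(20, 20),
#'                mig_edges = rbind(c(1, 2), c(2, 1)))
#' p <- param_set(m, theta = 0.01, mig = 100)
#' lineage_survival_fraction(m, p, tau_grid = c(0.01, 0.04), reps = 50,
#'                           seed = 1)
#' @export
lineage_survival_fraction <- function(model, params, tau_grid, reps = 1000L,
                                      seed = NULL) {
  stopifnot(reps >= 1, all(tau_grid >= 0))
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- sum(model$sample_counts)
  stop_at <- max(tau_grid)
  surv <- matrix(FALSE, reps, length(tau_grid))
  for (r in seq_len(reps)) {
    ct <- sim_coalescence_times(model, params, stop_time = stop_at)
    # >= 2 lineages at tau  <=>  fewer than n - 1 coalescences before tau
    surv[r, ] <- vapply(tau_grid, function(tau) sum(ct < tau) < n - 1L,
                        TRUE)
  }
  tibble(tau = tau_grid, frac_surviving = colMeans(surv), reps = reps)
}
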