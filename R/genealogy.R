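# Event-augmented genealogies.
#
# A genealogy is an ultrametric binary coalescent tree (tips at time 0,
# node times increasing into the past) whose branches carry time-stamped
# label-switch events: migrations (reversible, along declared migration
# edges) and divergences (irreversible, derived -> ancestral). Nodes are
# indexed 1..n for tips and n+1..2n-1 for coalescences; an event is stored
# against the child node of the branch it sits on.
#
# The probability density of a genealogy given the rate parameters is a
# product over the global time intervals delimited by every coalescence and
# every event: each interval contributes the survival of all competing
# risks (constant coalescent + migration rates, and the truncated-normal
# divergence hazard integrated over the interval once per at-risk derived
# lineage) times the rate of the specific event that ends it (2/Theta_i for
# the observed coalescing pair, M_ji for the observed migration, the
# divergence hazard at the event time for the observed label switch).

new_event_genealogy <- function(n_tips, tip_labels, tip_pop, parent,
                                node_time, node_pop, events, locus = 1L) {
  structure(
    list(n_tips = as.integer(n_tips), tip_labels = tip_labels,
         tip_pop = as.integer(tip_pop), parent = as.integer(parent),
         node_time = as.numeric(node_time), node_pop = as.integer(node_pop),
         events = events, locus = locus),
    class = "event_genealogy")
}

empty_events <- function() {
  data.frame(node = integer(0), time = numeric(0), kind = character(0),
             from = integer(0), to = integer(0))
}

#' Construct an event-augmented genealogy
#'
#' Low-level constructor; [simulate_genealogy()] is the usual way to obtain
#' one. Node indices: tips `1..n`, internal nodes `n+1..2n-1`.
#'
#' @param tip_labels character vector of tip names.
#' @param tip_pop integer (or label) population of each tip.
#' @param parent integer vector of length `2n-1`; `parent[v]` is the node
#'   above `v`, `0` for the root.
#' @param node_time numeric vector of length `2n-1`; tips must be at 0.
#' @param node_pop population index of the lineage at each node's own time.
#' @param events data frame with columns `node` (child node of the branch
#'   carrying the event), `time`, `kind` (`"migration"`/`"divergence"`),
#'   `from`, `to` (population indices; the lineage's label switches from
#'   `from` to `to` going backward in time).
#' @param model optional [pop_model()]; when given the genealogy is
#'   validated and construction fails with the violations listed.
#' @param locus locus identifier.
#' @return an `event_genealogy`.
#' @export
event_genealogy <- function(tip_labels, tip_pop, parent, node_time,
                            node_pop, events = empty_events(),
                            model = NULL, locus = 1L) {
  n <- length(tip_labels)
  g <- new_event_genealogy(n, tip_labels, tip_pop, parent, node_time,
                           node_pop, events, locus)
  if (!is.null(model)) {
    v <- validate_genealogy(g, model)
    if (length(v)) stop("invalid genealogy:\n  ", paste(v, collapse = "\n  "))
  }
  g
}

#' @export
print.event_genealogy <- function(x, ...) {
  cat(sprintf(
    "Event genealogy: %d tips, root at t = %.6g, %d event(s), locus %s\n",
    x$n_tips, max(x$node_time), nrow(x$events), x$locus))
  invisible(x)
}

root_node <- function(g) which(g$parent == 0L)

children_of <- function(g) {
  ch <- vector("list", length(g$parent))
  for (v in seq_along(g$parent)) {
    p <- g$parent[v]
    if (p > 0) ch[[p]] <- c(ch[[p]], v)
  }
  ch
}

# label of the lineage above node v just after applying events up to time t
label_at <- function(g, v, t) {
  lab <- g$node_pop[v]
  ev <- g$events[g$events$node == v & g$events$time <= t, , drop = FALSE]
  if (nrow(ev)) lab <- ev$to[order(ev$time)][nrow(ev)]
  lab
}

#' Validate an event genealogy against a population model
#'
#' Returns every invariant violation as a character vector (empty when the
#' genealogy is valid): ultrametricity, parent/child time ordering, event
#' times strictly increasing within a branch and contained in it, label
#' consistency along every lineage and at every coalescence, and event
#' legality under the model's migration and divergence edges (divergence
#' switches never reverse).
#'
#' @param g an [event_genealogy()].
#' @param model a [pop_model()].
#' @return character vector of violations.
#' @export
validate_genealogy <- function(g, model) {
  v <- character(0)
  n <- g$n_tips
  m <- 2L * n - 1L
  if (length(g$parent) != m || length(g$node_time) != m ||
      length(g$node_pop) != m) {
    return("node vectors do not have length 2*n_tips - 1")
  }
  if (sum(g$parent == 0L) != 1L) v <- c(v, "genealogy must have one root")
  if (any(g$node_time[seq_len(n)] != 0)) {
    v <- c(v, "tips must be at time 0 (ultrametric, contemporary sampling)")
  }
  ch <- children_of(g)
  intern <- setdiff(seq_len(m), seq_len(n))
  if (any(vapply(ch[intern], length, 1L) != 2L)) {
    v <- c(v, "every internal node must have exactly two children")
  }
  for (w in seq_len(m)) {
    p <- g$parent[w]
    if (p > 0 && g$node_time[p] < g$node_time[w]) {
      v <- c(v, sprintf("node %d is older than its parent", w))
    }
  }
  if (any(g$tip_pop < 1 | g$tip_pop > model$n_pop) ||
      any(g$node_pop < 1 | g$node_pop > model$n_pop)) {
    v <- c(v, "node population labels outside the model")
  }
  if (any(g$node_pop[seq_len(n)] != g$tip_pop)) {
    v <- c(v, "tip node labels disagree with the declared tip populations")
  }
  ev <- g$events
  if (nrow(ev)) {
    for (w in unique(ev$node)) {
      e <- ev[ev$node == w, , drop = FALSE]
      e <- e[order(e$time), , drop = FALSE]
      p <- g$parent[w]
      if (any(diff(e$time) <= 0)) {
        v <- c(v, sprintf("events on branch above node %d not strictly increasing", w))
      }
      if (any(e$time <= g$node_time[w]) ||
          (p > 0 && any(e$time >= g$node_time[p]))) {
        v <- c(v, sprintf("event time outside branch above node %d", w))
      }
      lab <- g$node_pop[w]
      for (r in seq_len(nrow(e))) {
        if (e$from[r] != lab) {
          v <- c(v, sprintf("event label mismatch on branch above node %d", w))
        }
        legal <- if (e$kind[r] == "migration") {
          any(model$mig_edges[, 1] == e$to[r] & model$mig_edges[, 2] == e$from[r])
        } else {
          any(model$div_edges[, 1] == e$from[r] & model$div_edges[, 2] == e$to[r])
        }
        if (!legal) {
          v <- c(v, sprintf("illegal %s event %s -> %s on branch above node %d",
                            e$kind[r], model$labels[e$from[r]],
                            model$labels[e$to[r]], w))
        }
        lab <- e$to[r]
      }
    }
  }
  # coalescences join two lineages that carry the same label at that time
  for (p in intern) {
    kids <- ch[[p]]
    if (length(kids) != 2L) next
    labs <- vapply(kids, function(w) label_at(g, w, g$node_time[p]), 1L)
    if (labs[1] != labs[2] || labs[1] != g$node_pop[p]) {
      v <- c(v, sprintf("coalescence at node %d joins labels %d and %d (node labeled %d)",
                        p, labs[1], labs[2], g$node_pop[p]))
    }
  }
  v
}

#' Coalescent rate for k lineages
#'
#' Total pairwise coalescence rate `k (k - 1) / Theta` in a population of
#' mutation-scaled size `Theta`, in mutation-scaled time.
#'
#' @param k number of lineages, `>= 0`; vectorized.
#' @param theta mutation-scaled population size, `> 0`.
#' @return rate(s); 0 for `k <= 1`.
#' @export
coalescent_rate <- function(k, theta) {
  if (any(theta <= 0)) stop("theta must be > 0")
  k * (k - 1) / theta
}

#' Total migration rate for a lineage configuration
#'
#' `sum_i k_i * sum_j M_ji` over populations `i` and their declared
#' immigration sources `j`.
#'
#' @param counts integer vector of lineage counts per population.
#' @param params a [param_set()].
#' @param model a [pop_model()].
#' @return total backward-time migration rate.
#' @export
migration_total_rate <- function(counts, params, model) {
  stopifnot(length(counts) == model$n_pop)
  sum(counts * incoming_mig_rate(model, params))
}

# Interval decomposition: one entry per global happening (coalescence or
# label-switch event), in time order. K holds the per-population lineage
# counts during the interval ending at the happening. Event codes:
# 1 = coalescence (pidx = population), 2 = migration (pidx = migration
# edge row, NA for an undeclared edge), 3 = divergence (pidx = divergence
# edge row). Everything here is parameter-independent, so a cached
# decomposition can be re-priced at new parameter values cheaply.
genealogy_intervals <- function(g, model) {
  n <- g$n_tips
  np <- model$n_pop
  ev <- g$events
  ne <- nrow(ev)
  time <- c(g$node_time[-seq_len(n)], ev$time)
  code <- c(rep(1L, n - 1L), ifelse(ev$kind == "migration", 2L, 3L))
  i <- c(g$node_pop[-seq_len(n)], ev$from)
  j <- c(rep(NA_integer_, n - 1L), ev$to)
  ord <- order(time)
  time <- time[ord]; code <- code[ord]; i <- i[ord]; j <- j[ord]
  nh <- length(time)
  if (nh == 0L) {
    return(list(t0 = numeric(0), u = numeric(0),
                K = matrix(0L, 0, np), code = integer(0),
                pidx = integer(0), time = numeric(0)))
  }
  # per-population count increments applied AFTER each happening
  inc <- matrix(0L, nh, np)
  inc[cbind(seq_len(nh), i)] <- -1L
  sw <- which(code != 1L)
  inc[cbind(sw, j[sw])] <- inc[cbind(sw, j[sw])] + 1L
  cs <- apply(inc, 2, cumsum)
  if (nh == 1L) cs <- matrix(cs, 1L)
  K <- sweep(rbind(rep(0L, np), cs[-nh, , drop = FALSE]), 2,
             tabulate(g$tip_pop, np), "+")
  t0 <- c(0, time[-nh])
  # resolve the parameter index of each event once (integer edge keys)
  pidx <- i
  if (any(code == 2L)) {
    key_e <- (model$mig_edges[, 1] - 1L) * np + model$mig_edges[, 2]
    w <- code == 2L
    pidx[w] <- match((j[w] - 1L) * np + i[w], key_e)
  }
  if (any(code == 3L)) {
    key_d <- (model$div_edges[, 1] - 1L) * np + model$div_edges[, 2]
    w <- code == 3L
    pidx[w] <- match((i[w] - 1L) * np + j[w], key_d)
  }
  list(t0 = t0, u = time - t0, K = K, code = code, pidx = pidx,
       time = time)
}

# survival exponent and event factor for a set of intervals, vectorized
intervals_log_density <- function(iv, params, model) {
  if (anyNA(iv$pidx)) return(-Inf)   # event on an undeclared edge
  lam_c <- as.numeric((iv$K * (iv$K - 1L)) %*% (1 / params$theta))
  lam_m <- as.numeric(iv$K %*% incoming_mig_rate(model, params))
  ll <- -sum(iv$u * (lam_c + lam_m))
  # divergence survival: one cumulative hazard per at-risk derived lineage
  nd <- length(params$tau_mean)
  for (e in seq_len(nd)) {
    kd <- iv$K[, model$div_edges[e, 1]]
    act <- kd > 0L & iv$u > 0
    if (any(act)) {
      if (any(iv$time[act] > params$b1[e])) return(-Inf)
      ll <- ll - sum(kd[act] * .cumhaz(iv$t0[act], iv$u[act],
                                       params$tau_mean[e],
                                       params$tau_sd[e], params$b1[e]))
    }
  }
  wc <- iv$code == 1L
  if (any(wc)) ll <- ll + sum(log(2 / params$theta[iv$pidx[wc]]))
  wm <- iv$code == 2L
  if (any(wm)) {
    r <- params$mig[iv$pidx[wm]]
    if (any(r == 0)) return(-Inf)
    ll <- ll + sum(log(r))
  }
  wd <- which(iv$code == 3L)
  if (length(wd)) {
    if (any(iv$time[wd] >= params$b1[iv$pidx[wd]])) return(-Inf)
    for (e in unique(iv$pidx[wd])) {
      te <- iv$time[wd[iv$pidx[wd] == e]]
      ll <- ll + sum(log(.haz(te, params$tau_mean[e], params$tau_sd[e],
                              params$b1[e])))
    }
  }
  ll
}

#' Log density of one genealogy interval
#'
#' Probability density contribution of a single time interval of length `u`
#' starting at `t0` with per-population lineage counts `counts`, ending in
#' the described event: survival of all competing risks times the rate of
#' the specific terminating event.
#'
#' @param t0 interval start time.
#' @param u interval length.
#' @param counts integer lineage counts per population at `t0`.
#' @param event list with `kind` (`"coalescence"`, `"migration"`,
#'   `"divergence"`), `i` (population of a coalescence, or the `from`
#'   label of a switch) and, for switches, `j` (the `to` label).
#' @param params a [param_set()].
#' @param model a [pop_model()].
#' @return log density; `-Inf` for an event that is impossible under the
#'   model (for example a migration with rate 0).
#' @export
interval_log_density <- function(t0, u, counts, event, params, model) {
  stopifnot(u >= 0, length(counts) == model$n_pop)
  code <- match(event$kind, c("coalescence", "migration", "divergence"))
  if (is.na(code)) stop("unknown event kind: ", event$kind)
  pidx <- if (code == 1L) event$i else if (code == 2L) {
    w <- which(model$mig_edges[, 1] == event$j &
               model$mig_edges[, 2] == event$i)
    if (length(w)) w else NA_integer_
  } else {
    w <- which(model$div_edges[, 1] == event$i &
               model$div_edges[, 2] == event$j)
    if (length(w)) w else NA_integer_
  }
  iv <- list(t0 = t0, u = u, K = matrix(as.integer(counts), 1),
             code = code, pidx = pidx, time = t0 + u)
  intervals_log_density(iv, params, model)
}

#' Log probability density of a genealogy given the parameters
#'
#' Product over all time intervals (delimited by every coalescence and
#' label-switch event) of the interval densities; accumulated in log space.
#'
#' @param g an [event_genealogy()].
#' @param params a [param_set()].
#' @param model a [pop_model()].
#' @param validate check the genealogy invariants first (error listing the
#'   violations if they fail).
#' @return log density.
#' @export
genealogy_log_density <- function(g, params, model, validate = FALSE) {
  if (validate) {
    v <- validate_genealogy(g, model)
    if (length(v)) stop("invalid genealogy:\n  ", paste(v, collapse = "\n  "))
  }
  intervals_log_density(genealogy_intervals(g, model), params, model)
}

#' Convert an event genealogy to an ape "phylo" tree
#'
#' Drops the event annotations; branch lengths are in mutation-scaled time.
#'
#' @param x an [event_genealogy()].
#' @param ... unused.
#' @return an [ape::as.phylo] object.
#' @export
as.phylo.event_genealogy <- function(x, ...) {
  n <- x$n_tips
  m <- 2L * n - 1L
  r <- root_node(x)
  # ape numbering: tips 1..n unchanged, root n+1, other internals follow
  intern <- c(r, setdiff((n + 1L):m, r))
  map <- integer(m)
  map[seq_len(n)] <- seq_len(n)
  map[intern] <- n + seq_along(intern)
  nonroot <- setdiff(seq_len(m), r)
  edge <- cbind(map[x$parent[nonroot]], map[nonroot])
  len <- x$node_time[x$parent[nonroot]] - x$node_time[nonroot]
  tr <- structure(list(edge = edge, edge.length = len, Nnode = n - 1L,
                       tip.label = x$tip_labels),
                  class = "phylo")
  ape::reorder.phylo(tr, "cladewise")
}
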