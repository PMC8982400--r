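# Metropolis-Hastings sampling of genealogies and parameters.
#
# The state is (parameters, one event genealogy per locus). Parameter
# updates are sliding-window proposals on the log scale (reflected at the
# prior bounds); they touch only the genealogy-density term, which is
# recomputed from cached interval decompositions. Genealogy updates detach
# one lineage and re-simulate its event path backward with the
# competing-draws scheme until it re-coalesces; the Hastings ratio uses the
# explicitly computed path proposal densities in both directions, so no
# cancellation between target and proposal is assumed.

#' Prior specification
#'
#' One prior per parameter class: `"uniform"` with bounds, or
#' `"exponential"` with a mean and an upper bound (truncated).
#'
#' @param model a [pop_model()].
#' @param theta,mig,tau_mean,tau_sd priors for the parameter classes, each
#'   a list `list(dist = "uniform", min =, max =)` or
#'   `list(dist = "exponential", mean =, upper =)`. Classes absent from
#'   the model may be `NULL`.
#' @return an object of class `prior_spec` mapping every scalar parameter
#'   to its prior.
#' @export
prior_spec <- function(model,
                       theta = list(dist = "uniform", min = 1e-4, max = 0.1),
                       mig = list(dist = "uniform", min = 0.01, max = 1000),
                       tau_mean = list(dist = "exponential", mean = 0.01,
                                       upper = 0.1),
                       tau_sd = list(dist = "uniform", min = 1e-6,
                                     max = 0.01)) {
  stopifnot(inherits(model, "pop_model"))
  chk <- function(p, what) {
    if (is.null(p)) return(NULL)
    stopifnot(p$dist %in% c("uniform", "exponential"))
    if (p$dist == "uniform") {
      stopifnot(p$min > 0 || what == "mig", p$min >= 0, p$max > p$min)
    } else {
      stopifnot(p$mean > 0, p$upper > 0)
    }
    p
  }
  prm <- list()
  for (i in seq_len(model$n_pop)) {
    prm[[paste0("theta_", model$labels[i])]] <- chk(theta, "theta")
  }
  if (nrow(model$mig_edges)) {
    for (r in seq_len(nrow(model$mig_edges))) {
      prm[[sprintf("M_%s_%s", model$labels[model$mig_edges[r, 1]],
                   model$labels[model$mig_edges[r, 2]])]] <- chk(mig, "mig")
    }
  }
  if (nrow(model$div_edges)) {
    for (r in seq_len(nrow(model$div_edges))) {
      lab <- model$labels[model$div_edges[r, 1]]
      prm[[paste0("tau_mean_", lab)]] <- chk(tau_mean, "tau_mean")
      prm[[paste0("tau_sd_", lab)]] <- chk(tau_sd, "tau_sd")
    }
  }
  structure(list(model = model, priors = prm), class = "prior_spec")
}

prior_support <- function(p) {
  if (p$dist == "uniform") c(p$min, p$max) else c(0, p$upper)
}

prior_logdens <- function(x, p) {
  s <- prior_support(p)
  out <- rep(-Inf, length(x))
  ok <- x >= s[1] & x <= s[2]
  if (p$dist == "uniform") {
    out[ok] <- -log(s[2] - s[1])
  } else {
    out[ok] <- dexp(x[ok], 1 / p$mean, log = TRUE) -
      pexp(p$upper, 1 / p$mean, log.p = TRUE)
  }
  out
}

prior_draw <- function(p, n = 1) {
  if (p$dist == "uniform") {
    runif(n, p$min, p$max)
  } else {
    qexp(runif(n) * pexp(p$upper, 1 / p$mean), 1 / p$mean)
  }
}

prior_median <- function(p) {
  if (p$dist == "uniform") (p$min + p$max) / 2 else
    qexp(0.5 * pexp(p$upper, 1 / p$mean), 1 / p$mean)
}

# flatten a param_set to the prior_spec's named vector and back
param_vector <- function(params, model) {
  v <- c(setNames(as.numeric(params$theta),
                  paste0("theta_", model$labels)))
  if (nrow(model$mig_edges)) {
    v <- c(v, setNames(params$mig,
                       sprintf("M_%s_%s", model$labels[model$mig_edges[, 1]],
                               model$labels[model$mig_edges[, 2]])))
  }
  if (nrow(model$div_edges)) {
    lab <- model$labels[model$div_edges[, 1]]
    v <- c(v, setNames(params$tau_mean, paste0("tau_mean_", lab)),
           setNames(params$tau_sd, paste0("tau_sd_", lab)))
  }
  v
}

vector_to_params <- function(v, model, b1 = Inf) {
  nm <- nrow(model$mig_edges)
  nd <- nrow(model$div_edges)
  theta <- unname(v[paste0("theta_", model$labels)])
  structure(list(
    theta = setNames(theta, model$labels),
    mig = if (nm) unname(v[sprintf("M_%s_%s",
                                   model$labels[model$mig_edges[, 1]],
                                   model$labels[model$mig_edges[, 2]])])
          else numeric(0),
    tau_mean = if (nd) unname(v[paste0("tau_mean_",
                                       model$labels[model$div_edges[, 1]])])
               else numeric(0),
    tau_sd = if (nd) unname(v[paste0("tau_sd_",
                                     model$labels[model$div_edges[, 1]])])
             else numeric(0),
    b1 = if (nd) rep_len(b1, nd) else numeric(0)),
    class = "param_set")
}

#' Log posterior kernel
#'
#' `log p(rho) + sum over loci [log f(G_l | rho) + log p(D_l | G_l)]`.
#' With `data = NULL` the likelihood term is dropped (prior-only runs used
#' to check sampler correctness).
#'
#' @param gs list of [event_genealogy()], one per locus.
#' @param params a [param_set()].
#' @param data a `coaldiv_data` (or `NULL`).
#' @param model a [pop_model()].
#' @param priors a [prior_spec()].
#' @param mut a [mutation_model()].
#' @return log kernel value; `-Inf` outside the prior support.
#' @export
log_posterior_kernel <- function(gs, params, data, model, priors,
                                 mut = mutation_model()) {
  v <- param_vector(params, model)
  lp <- sum(vapply(names(v), function(nm)
    prior_logdens(v[[nm]], priors$priors[[nm]]), 1))
  if (!is.finite(lp)) return(-Inf)
  for (l in seq_along(gs)) {
    lp <- lp + genealogy_log_density(gs[[l]], params, model)
    if (!is.null(data)) {
      lp <- lp + pruning_loglike(gs[[l]], data$alignments[[l]], mut)
    }
  }
  lp
}

# Data-informed starting genealogy: UPGMA on JC69 distances gives an
# ultrametric tree. For each derived population a split time tau_hat is
# estimated as 0.9 times the smallest cross-population pair height, and
# the tree is labeled as a hard split: single-population subtrees below
# tau_hat keep their population's label, and each such lineage switches
# (through its divergence chain) at tau_hat on the branch that crosses
# it. The chain relabels and reshapes from there. Fails (and the caller
# falls back to a prior-process start) when the divergence chains have no
# single terminal population.
init_genealogy_from_data <- function(aln, tip_labels, tip_pop, model,
                                     b1, locus = 1L) {
  n <- length(tip_labels)
  term <- function(i) {   # follow divergence edges to their end
    repeat {
      w <- which(model$div_edges[, 1] == i)
      if (!length(w)) return(i)
      i <- model$div_edges[w, 2]
    }
  }
  terms <- vapply(seq_len(model$n_pop), term, 1L)
  if (length(unique(terms)) != 1L) stop("no common terminal population")
  sink <- terms[1]
  d <- as.matrix(ape::dist.dna(
    ape::as.DNAbin(tolower(aln[tip_labels, , drop = FALSE])),
    model = "JC69", pairwise.deletion = TRUE))
  d[!is.finite(d)] <- max(d[is.finite(d)], 0.01)
  hc <- stats::hclust(stats::as.dist(d) / 2, method = "average")
  h <- hc$height
  eps <- max(max(h), 1e-4) * 1e-6
  for (k in seq_along(h)) h[k] <- max(h[k], if (k > 1) h[k - 1] + eps else eps)
  # split-time guesses: cross-population pairs cannot merge below the split
  tau_hat <- rep(NA_real_, model$n_pop)
  for (i in seq_len(model$n_pop)) {
    if (i == sink || !sum(tip_pop == i)) next
    cross <- d[tip_pop == i, tip_pop != i, drop = FALSE] / 2
    tau_hat[i] <- max(0.9 * unname(quantile(cross, 0.05)), eps)
    if (is.finite(b1)) tau_hat[i] <- min(tau_hat[i], 0.9 * b1)
  }
  parent <- integer(2L * n - 1L)
  node_time <- numeric(2L * n - 1L)
  node_pop <- integer(2L * n - 1L)
  node_pop[seq_len(n)] <- tip_pop
  for (k in seq_len(n - 1L)) {
    v <- n + k
    node_time[v] <- h[k]
    for (m2 in hc$merge[k, ]) {
      parent[if (m2 < 0) -m2 else n + m2] <- v
    }
  }
  # hard-split labeling: a node keeps label L if both children carry L and
  # the node sits below L's split guess; otherwise it is ancestral and the
  # non-ancestral child lineages switch on their branches
  ch <- vector("list", 2L * n - 1L)
  for (v in seq_len(2L * n - 1L)) {
    p <- parent[v]
    if (p > 0) ch[[p]] <- c(ch[[p]], v)
  }
  ev <- empty_events()
  for (v in (n + 1L):(2L * n - 1L)) {
    labs <- node_pop[ch[[v]]]
    if (labs[1] == labs[2] &&
        (labs[1] == sink ||
         (!is.na(tau_hat[labs[1]]) && node_time[v] < tau_hat[labs[1]]))) {
      node_pop[v] <- labs[1]
      next
    }
    node_pop[v] <- sink
    for (w in ch[[v]]) {
      lab <- node_pop[w]
      if (lab == sink) next
      lo <- node_time[w]; hi <- node_time[v]
      steps <- integer(0); i <- lab
      while (i != sink) {
        we <- which(model$div_edges[, 1] == i)
        steps <- c(steps, we)
        i <- model$div_edges[we, 2]
      }
      base <- min(max(tau_hat[lab], lo + (hi - lo) * 0.05, na.rm = TRUE),
                  lo + (hi - lo) * 0.5)
      times <- base + (hi - base) * 0.4 *
        (seq_along(steps) - 1) / max(length(steps), 1)
      times <- pmin(pmax(times, lo + (hi - lo) * 0.02),
                    hi - (hi - lo) * 0.02)
      times <- sort(times) + (seq_along(times) - 1) * (hi - lo) * 1e-6
      for (q in seq_along(steps)) {
        to <- model$div_edges[steps[q], 2]
        ev <- rbind(ev, data.frame(node = w, time = times[q],
                                   kind = "divergence", from = lab,
                                   to = to))
        lab <- to
      }
    }
  }
  g <- new_event_genealogy(n, tip_labels, tip_pop, parent, node_time,
                           node_pop, ev, locus)
  attr(g, "tau_hat") <- tau_hat
  g
}

# translate all divergence events of one edge by delta across loci;
# NULL when any event would leave its branch, cross another event on the
# same branch, or become non-positive
shift_divergence_events <- function(gs, model, e, delta) {
  dd <- model$div_edges[e, 1]; da <- model$div_edges[e, 2]
  out <- gs
  for (l in seq_along(gs)) {
    g <- gs[[l]]
    ev <- g$events
    w <- which(ev$kind == "divergence" & ev$from == dd & ev$to == da)
    if (!length(w)) next
    nt <- ev$time
    nt[w] <- nt[w] + delta
    if (any(nt[w] <= 0)) return(NULL)
    pa <- g$parent[ev$node[w]]
    if (any(nt[w] <= g$node_time[ev$node[w]]) ||
        any(nt[w] >= g$node_time[pa])) return(NULL)
    for (b in unique(ev$node[w])) {
      bw <- which(ev$node == b)
      if (length(bw) > 1L) {
        if (!identical(order(ev$time[bw]), order(nt[bw])) ||
            anyDuplicated(nt[bw])) return(NULL)
      }
    }
    g$events$time <- nt
    o <- order(g$events$node, g$events$time)
    g$events <- g$events[o, , drop = FALSE]
    out[[l]] <- g
  }
  out
}

# stack per-locus interval decompositions so the parameter sweep can price
# all loci in one vectorized pass
concat_intervals <- function(ivs) {
  list(t0 = unlist(lapply(ivs, `[[`, "t0")),
       u = unlist(lapply(ivs, `[[`, "u")),
       K = do.call(rbind, lapply(ivs, `[[`, "K")),
       code = unlist(lapply(ivs, `[[`, "code")),
       pidx = unlist(lapply(ivs, `[[`, "pidx")),
       time = unlist(lapply(ivs, `[[`, "time")))
}

## ---- genealogy proposal -------------------------------------------------

subtree_nodes <- function(g, c) {
  ch <- children_of(g)
  out <- integer(0)
  stack <- c
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    out <- c(out, v)
    stack <- c(stack, ch[[v]])
  }
  out
}

# events of one branch as plain vectors (kind codes: 2 migration,
# 3 divergence), time-ordered
branch_path <- function(ev, node) {
  w <- which(ev$node == node)
  w <- w[order(ev$time[w])]
  list(time = ev$time[w],
       kind = ifelse(ev$kind[w] == "migration", 2L, 3L),
       from = ev$from[w], to = ev$to[w])
}

empty_path <- function() {
  list(time = numeric(0), kind = integer(0), from = integer(0),
       to = integer(0))
}

# Split g into the detached unit (subtree at c plus the path above c) and
# the background rest-tree. Returns everything path_process() needs.
detach_lineage <- function(g, c) {
  r <- root_node(g)
  stopifnot(c != r)
  p <- g$parent[c]
  ch <- children_of(g)
  s <- setdiff(ch[[p]], c)
  gp <- g$parent[p]
  sub <- subtree_nodes(g, c)

  ev <- g$events
  path_ev <- branch_path(ev, c)
  keep <- ev$node != c
  ext_ev <- empty_path()
  bg_node <- ev$node[keep]
  if (gp == 0L) {
    # p was the root: s becomes the background root; s's old branch events
    # move above the background root (they sit on the re-simulated segment)
    ext_ev <- branch_path(ev, s)
    drop2 <- bg_node == s
    keep2 <- !drop2
    bg_ev <- list(node = bg_node[keep2], time = ev$time[keep][keep2],
                  kind = ev$kind[keep][keep2], from = ev$from[keep][keep2],
                  to = ev$to[keep][keep2])
  } else {
    # splice p out: s inherits p's parent and p's branch events
    bg_node[bg_node == p] <- s
    bg_ev <- list(node = bg_node, time = ev$time[keep],
                  kind = ev$kind[keep], from = ev$from[keep],
                  to = ev$to[keep])
  }
  bg_parent <- g$parent
  bg_parent[s] <- gp
  bg_parent[c] <- 0L
  bg_parent[p] <- NA_integer_   # removed
  bg_nodes <- setdiff(seq_along(g$parent), c(sub, p))
  bg_root <- if (gp == 0L) s else r

  # attachment record for the reverse path
  attach <- list(time = g$node_time[p], label = g$node_pop[p],
                 partner = if (gp == 0L) "ext" else s)
  list(p = p, s = s, c = c, sub = sub,
       bg_parent = bg_parent, bg_nodes = bg_nodes, bg_root = bg_root,
       bg_ev = bg_ev, path_ev = path_ev, ext_ev = ext_ev, attach = attach)
}

# Background description for the competing-draws path process: per-edge
# sub-segments with labels, plus the root extension start label.
background_segments <- function(g, det) {
  nodes <- setdiff(det$bg_nodes, det$bg_root)
  nb <- length(nodes)
  sn <- vector("list", nb); sa <- vector("list", nb)
  sb <- vector("list", nb); sl <- vector("list", nb)
  for (q in seq_len(nb)) {
    w <- nodes[q]
    a <- g$node_time[w]
    b <- g$node_time[det$bg_parent[w]]
    we <- which(det$bg_ev$node == w)
    if (length(we)) {
      we <- we[order(det$bg_ev$time[we])]
      ts <- c(a, det$bg_ev$time[we], b)
      labs <- c(g$node_pop[w], det$bg_ev$to[we])
    } else {
      ts <- c(a, b)
      labs <- g$node_pop[w]
    }
    ns <- length(labs)
    sn[[q]] <- rep(w, ns); sa[[q]] <- ts[seq_len(ns)]
    sb[[q]] <- ts[-1L]; sl[[q]] <- labs
  }
  list(node = unlist(sn), a = unlist(sa), b = unlist(sb),
       lab = unlist(sl),
       root_time = g$node_time[det$bg_root],
       root_lab = g$node_pop[det$bg_root])
}

# The path process: the competing-draws simulation of one detached lineage
# (and, past the background root, of the background root lineage as well)
# until re-coalescence. mode "simulate" draws a new path and returns its
# log proposal density; mode "evaluate" replays the recorded old path and
# returns its log proposal density under the same process.
path_process <- function(g, det, params, model, mode, max_steps = 10000L) {
  bseg <- background_segments(g, det)
  inc <- incoming_mig_rate(model, params)
  theta <- unname(params$theta)
  tm <- params$tau_mean; sdv <- params$tau_sd; b1 <- params$b1
  dd <- model$div_edges[, 1]; da <- model$div_edges[, 2]
  nd <- length(tm)
  simulate <- mode == "simulate"

  t_ml0 <- g$node_time[det$c]   # moving lineage exists above this time
  lab_ml <- g$node_pop[det$c]
  root_time <- bseg$root_time   # background root extension starts here
  lab_ext <- bseg$root_lab
  t <- min(t_ml0, root_time)
  chg <- sort(unique(c(bseg$a, bseg$b)))
  chg <- chg[chg > t & chg < Inf]
  ci <- 1L   # pointer into chg

  logq <- 0
  nm_t <- numeric(0); nm_k <- integer(0); nm_f <- integer(0); nm_o <- integer(0)
  ne_t <- numeric(0); ne_k <- integer(0); ne_f <- integer(0); ne_o <- integer(0)
  if (!simulate) {
    ev_ml <- det$path_ev; im <- 1L
    ev_ext <- det$ext_ev; ie <- 1L
    att <- det$attach
  }
  # survival contribution of the active moving lineage(s) over [a, b]
  surv <- function(a, b, lab_ml, lab_ext, n_part, ml_on, ext_on) {
    if (b <= a) return(0)
    lam <- (if (ml_on) n_part * 2 / theta[lab_ml] + inc[lab_ml] else 0) +
      (if (ext_on) inc[lab_ext] else 0)
    out <- -(b - a) * lam
    for (e in seq_len(nd)) {
      nr <- (ml_on && lab_ml == dd[e]) + (ext_on && lab_ext == dd[e])
      if (nr > 0) {
        if (b > b1[e]) return(-Inf)
        out <- out - nr * .cumhaz(a, b - a, tm[e], sdv[e], b1[e])
      }
    }
    out
  }
  it <- 0L
  repeat {
    it <- it + 1L
    if (it > max_steps) return(list(ok = FALSE, reason = "step cap"))
    ml_on <- t >= t_ml0
    ext_on <- t >= root_time
    joint <- ml_on && ext_on
    n_part <- if (!ml_on) 0L else if (ext_on) {
      as.integer(lab_ext == lab_ml)
    } else {
      sum(bseg$a <= t & bseg$b > t & bseg$lab == lab_ml)
    }
    while (ci <= length(chg) && chg[ci] <= t) ci <- ci + 1L
    t_next <- min(if (!joint && ci <= length(chg)) chg[ci] else Inf,
                  if (root_time > t) root_time else Inf,
                  if (t_ml0 > t) t_ml0 else Inf)

    if (simulate) {
      cand_t <- Inf; cand_kind <- 0L; cand_e <- 0L; cand_ext <- FALSE
      if (ml_on) {
        lam_ml <- n_part * 2 / theta[lab_ml] + inc[lab_ml]
        if (lam_ml > 0) {
          cand_t <- t + rexp(1, lam_ml)
          cand_kind <- if (runif(1) < n_part * 2 / theta[lab_ml] / lam_ml)
            1L else 2L
        }
        for (e in seq_len(nd)) {
          if (dd[e] != lab_ml || t >= b1[e]) next
          tt <- t + .sampdiv(t, runif(1), tm[e], sdv[e], b1[e])
          if (tt < cand_t) { cand_t <- tt; cand_kind <- 3L; cand_e <- e
                             cand_ext <- FALSE }
        }
      }
      if (ext_on) {
        if (inc[lab_ext] > 0) {
          tt <- t + rexp(1, inc[lab_ext])
          if (tt < cand_t) { cand_t <- tt; cand_kind <- 2L; cand_ext <- TRUE }
        }
        for (e in seq_len(nd)) {
          if (dd[e] != lab_ext || t >= b1[e]) next
          tt <- t + .sampdiv(t, runif(1), tm[e], sdv[e], b1[e])
          if (tt < cand_t) { cand_t <- tt; cand_kind <- 3L; cand_e <- e
                             cand_ext <- TRUE }
        }
      }
      if (cand_t >= t_next) {
        logq <- logq + surv(t, t_next, lab_ml, lab_ext, n_part, ml_on,
                            ext_on)
        t <- t_next
        next
      }
      logq <- logq + surv(t, cand_t, lab_ml, lab_ext, n_part, ml_on,
                          ext_on)
      t <- cand_t
      if (cand_kind == 1L) {
        if (joint) {
          partner <- "ext"
        } else {
          actw <- bseg$node[bseg$a < t & bseg$b >= t & bseg$lab == lab_ml]
          if (!length(actw)) return(list(ok = FALSE, reason = "no partner"))
          partner <- actw[sample.int(length(actw), 1)]
        }
        logq <- logq + log(2 / theta[lab_ml])
        return(list(ok = TRUE, logq = logq,
                    path_ev = list(time = nm_t, kind = nm_k, from = nm_f,
                                   to = nm_o),
                    ext_ev = list(time = ne_t, kind = ne_k, from = ne_f,
                                  to = ne_o),
                    attach = list(time = t, label = lab_ml,
                                  partner = partner)))
      } else if (cand_kind == 2L) {
        who_lab <- if (cand_ext) lab_ext else lab_ml
        el <- which(model$mig_edges[, 2] == who_lab & params$mig > 0)
        if (!length(el)) return(list(ok = FALSE, reason = "no mig edge"))
        pick <- el[sample.int(length(el), 1, prob = params$mig[el])]
        j <- model$mig_edges[pick, 1]
        logq <- logq + log(params$mig[pick])
        if (cand_ext) {
          ne_t <- c(ne_t, t); ne_k <- c(ne_k, 2L)
          ne_f <- c(ne_f, who_lab); ne_o <- c(ne_o, j)
          lab_ext <- j
        } else {
          nm_t <- c(nm_t, t); nm_k <- c(nm_k, 2L)
          nm_f <- c(nm_f, who_lab); nm_o <- c(nm_o, j)
          lab_ml <- j
        }
      } else {
        e <- cand_e
        logq <- logq + log(.haz(t, tm[e], sdv[e], b1[e]))
        if (cand_ext) {
          ne_t <- c(ne_t, t); ne_k <- c(ne_k, 3L)
          ne_f <- c(ne_f, dd[e]); ne_o <- c(ne_o, da[e])
          lab_ext <- da[e]
        } else {
          nm_t <- c(nm_t, t); nm_k <- c(nm_k, 3L)
          nm_f <- c(nm_f, dd[e]); nm_o <- c(nm_o, da[e])
          lab_ml <- da[e]
        }
      }
    } else {
      nxt_ml <- if (im <= length(ev_ml$time)) ev_ml$time[im] else Inf
      nxt_ext <- if (ie <= length(ev_ext$time)) ev_ext$time[ie] else Inf
      nxt <- min(nxt_ml, nxt_ext, att$time)
      if (nxt >= t_next && t_next < Inf) {
        logq <- logq + surv(t, t_next, lab_ml, lab_ext, n_part, ml_on,
                            ext_on)
        t <- t_next
        next
      }
      logq <- logq + surv(t, nxt, lab_ml, lab_ext, n_part, ml_on, ext_on)
      t <- nxt
      if (!is.finite(logq)) return(list(ok = TRUE, logq = -Inf))
      if (att$time == nxt) {
        if (!ml_on || att$label != lab_ml) {
          return(list(ok = TRUE, logq = -Inf))
        }
        if (identical(att$partner, "ext")) {
          if (lab_ext != lab_ml || !ext_on) return(list(ok = TRUE, logq = -Inf))
        } else if (ext_on) {
          return(list(ok = TRUE, logq = -Inf))
        } else {
          pok <- any(bseg$node == att$partner & bseg$a < t & bseg$b >= t &
                     bseg$lab == lab_ml)
          if (!pok) return(list(ok = TRUE, logq = -Inf))
        }
        logq <- logq + log(2 / theta[lab_ml])
        return(list(ok = TRUE, logq = logq))
      }
      if (nxt_ml <= nxt_ext) {
        if (!ml_on) return(list(ok = TRUE, logq = -Inf))
        kk <- ev_ml$kind[im]; ff <- ev_ml$from[im]; oo <- ev_ml$to[im]
        im <- im + 1L
        logq <- logq + replay_event_logq(nxt, kk, ff, oo, lab_ml, params,
                                         model, tm, sdv, b1, dd, da)
        lab_ml <- oo
      } else {
        if (!ext_on) return(list(ok = TRUE, logq = -Inf))
        kk <- ev_ext$kind[ie]; ff <- ev_ext$from[ie]; oo <- ev_ext$to[ie]
        ie <- ie + 1L
        logq <- logq + replay_event_logq(nxt, kk, ff, oo, lab_ext, params,
                                         model, tm, sdv, b1, dd, da)
        lab_ext <- oo
      }
      if (!is.finite(logq)) return(list(ok = TRUE, logq = -Inf))
    }
  }
}

replay_event_logq <- function(time, kind, from, to, lab, params, model,
                              tm, sdv, b1, dd, da) {
  if (from != lab) return(-Inf)
  if (kind == 2L) {
    idx <- which(model$mig_edges[, 1] == to & model$mig_edges[, 2] == lab)
    if (!length(idx) || params$mig[idx] == 0) return(-Inf)
    log(params$mig[idx])
  } else {
    idx <- which(dd == lab & da == to)
    if (!length(idx) || time >= b1[idx]) return(-Inf)
    log(.haz(time, tm[idx], sdv[idx], b1[idx]))
  }
}

# rebuild a full genealogy from the background plus a new path
reassemble_genealogy <- function(g, det, sim) {
  parent <- det$bg_parent
  node_time <- g$node_time
  node_pop <- g$node_pop
  p <- det$p           # reuse the removed node id for the new coalescence
  att <- sim$attach
  ev <- det$bg_ev
  ev_node <- ev$node; ev_time <- ev$time; ev_kind <- ev$kind
  ev_from <- ev$from; ev_to <- ev$to
  kind_str <- c(NA, "migration", "divergence")

  if (identical(att$partner, "ext")) {
    w <- det$bg_root
    parent[w] <- p
    parent[p] <- 0L
    # new events on the background root extension sit on w's new branch,
    # below the new root p
    keep <- sim$ext_ev$time < att$time
    if (any(keep)) {
      ev_node <- c(ev_node, rep(w, sum(keep)))
      ev_time <- c(ev_time, sim$ext_ev$time[keep])
      ev_kind <- c(ev_kind, kind_str[sim$ext_ev$kind[keep]])
      ev_from <- c(ev_from, sim$ext_ev$from[keep])
      ev_to <- c(ev_to, sim$ext_ev$to[keep])
    }
  } else {
    w <- att$partner
    pw <- parent[w]
    parent[w] <- p
    parent[p] <- pw
    # w's old events above the attachment move onto the new branch p -> pw
    up <- ev_node == w & ev_time > att$time
    ev_node[up] <- p
  }
  parent[det$c] <- p
  node_time[p] <- att$time
  node_pop[p] <- att$label
  nml <- length(sim$path_ev$time)
  if (nml) {
    ev_node <- c(ev_node, rep(det$c, nml))
    ev_time <- c(ev_time, sim$path_ev$time)
    ev_kind <- c(ev_kind, kind_str[sim$path_ev$kind])
    ev_from <- c(ev_from, sim$path_ev$from)
    ev_to <- c(ev_to, sim$path_ev$to)
  }
  o <- order(ev_node, ev_time)
  events <- data.frame(node = ev_node[o], time = ev_time[o],
                       kind = ev_kind[o], from = ev_from[o],
                       to = ev_to[o])
  new_event_genealogy(g$n_tips, g$tip_labels, g$tip_pop, parent, node_time,
                      node_pop, events, g$locus)
}

#' Propose a new genealogy by lineage re-simulation
#'
#' Detaches the branch above one randomly chosen non-root node and
#' re-simulates that lineage's event path backward in time with the
#' competing-draws scheme (exponential proposals for coalescence and
#' migration, survival inversion for divergence), against the fixed
#' remaining tree, until it re-coalesces. Past the old root the remaining
#' root lineage participates in the process as well, so label mismatches
#' resolve rather than deadlock. Returns the proposal together with the
#' log Hastings ratio component `log q(old path) - log q(new path)`.
#'
#' @param g an [event_genealogy()].
#' @param params a [param_set()].
#' @param model a [pop_model()].
#' @return list with `g` (proposed genealogy), `log_hastings`
#'   (`log q_reverse - log q_forward`), and `ok`; `ok = FALSE` flags a
#'   proposal that should be treated as rejected.
#' @export
propose_genealogy <- function(g, params, model) {
  r <- root_node(g)
  cand <- setdiff(seq_along(g$parent), r)
  c_node <- cand[sample.int(length(cand), 1)]
  det <- detach_lineage(g, c_node)
  sim <- path_process(g, det, params, model, mode = "simulate")
  if (!isTRUE(sim$ok)) return(list(ok = FALSE))
  rev <- path_process(g, det, params, model, mode = "evaluate")
  if (!isTRUE(rev$ok)) return(list(ok = FALSE))
  g2 <- reassemble_genealogy(g, det, sim)
  list(ok = TRUE, g = g2, log_hastings = rev$logq - sim$logq,
       node = c_node)
}

## ---- chain driver -------------------------------------------------------

#' Chain configuration
#'
#' @param iterations total MCMC iterations (one parameter sweep plus
#'   `genealogy_updates` genealogy moves each).
#' @param burnin iterations discarded (and used for proposal-window
#'   adaptation); must be `< iterations`.
#' @param thin record every `thin`-th post-burn-in iteration.
#' @param bins histogram bin count for posterior summaries (`>= 10`).
#' @param seed integer RNG seed.
#' @param genealogy_updates genealogy moves per iteration; default one
#'   per locus.
#' @return an object of class `chain_config`.
#' @export
chain_config <- function(iterations = 5000L, burnin = 1000L, thin = 2L,
                         bins = 1500L, seed = 1L,
                         genealogy_updates = NULL) {
  stopifnot(burnin < iterations, bins >= 10, thin >= 1)
  structure(list(iterations = as.integer(iterations),
                 burnin = as.integer(burnin), thin = as.integer(thin),
                 bins = as.integer(bins), seed = as.integer(seed),
                 genealogy_updates = genealogy_updates),
            class = "chain_config")
}

#' Run the Metropolis-Hastings sampler
#'
#' Samples parameters (mutation-scaled sizes, immigration rates,
#' divergence mean and spread) and per-locus genealogies. With
#' `likelihood = FALSE` (or `data = NULL`) the sequence likelihood is
#' dropped and the chain targets the prior times the genealogy density --
#' whose parameter marginal is the prior, a standard sampler-correctness
#' check.
#'
#' @param data a `coaldiv_data` from [simulate_dataset()] or
#'   [read_alignments()], or `NULL`.
#' @param model a [pop_model()].
#' @param priors a [prior_spec()].
#' @param chain a [chain_config()].
#' @param mut a [mutation_model()].
#' @param likelihood include the sequence-likelihood term?
#' @param b1 upper truncation bound for divergence distributions; defaults
#'   to the `tau_mean` prior's upper bound.
#' @param init_params optional starting [param_set()].
#' @param init_genealogies optional list of starting genealogies (one per
#'   locus); by default a data-informed UPGMA start is used when data are
#'   present, else a simulation from the starting parameters.
#' @param verbose print progress.
#' @return a `coaldiv_fit`: `samples` (tibble of retained draws),
#'   `summary` (posterior summaries per parameter, see
#'   [summarize_posterior()]), acceptance rates, the final genealogies,
#'   and the run settings.
#' @export
run_chain <- function(data, model, priors, chain = chain_config(),
                      mut = mutation_model(), likelihood = !is.null(data),
                      b1 = NULL, init_params = NULL,
                      init_genealogies = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "pop_model"), inherits(priors, "prior_spec"))
  set.seed(chain$seed)
  use_lik <- likelihood && !is.null(data)
  nloci <- if (!is.null(data)) length(data$alignments) else 1L
  gu <- if (is.null(chain$genealogy_updates)) nloci else
    chain$genealogy_updates

  pnames <- names(priors$priors)
  if (is.null(b1)) {
    td <- priors$priors[[grep("^tau_mean_", pnames)[1]]]
    b1 <- if (length(grep("^tau_mean_", pnames))) {
      3 * prior_support(td)[2]
    } else Inf
  }
  v <- if (!is.null(init_params)) param_vector(init_params, model) else
    vapply(pnames, function(nm) prior_median(priors$priors[[nm]]), 1)
  params <- vector_to_params(v, model, b1 = b1)

  # initial genealogies: simulated from the model at the starting values;
  # with data, tips are relabeled to the data's tip names (population by
  # population, so labels stay consistent)
  gs <- vector("list", nloci)
  tip_order <- NULL
  if (!is.null(data)) {
    if (!identical(tabulate(data$tip_pop, model$n_pop),
                   unname(model$sample_counts))) {
      stop("data sample counts per population do not match the model")
    }
    tip_order <- unlist(lapply(seq_len(model$n_pop), function(i)
      data$tip_labels[data$tip_pop == i]))
  }
  for (l in seq_len(nloci)) {
    g0 <- if (!is.null(init_genealogies)) init_genealogies[[l]]
    if (is.null(g0) && use_lik) {
      g0 <- tryCatch(
        init_genealogy_from_data(data$alignments[[l]], tip_order,
                                 rep(seq_len(model$n_pop),
                                     model$sample_counts),
                                 model, b1 = b1, locus = l),
        error = function(e) NULL)
      if (!is.null(g0) &&
          !is.finite(genealogy_log_density(g0, params, model))) {
        g0 <- NULL
      }
    }
    if (is.null(g0)) {
      g0 <- simulate_genealogy(model, params, locus = l)
      if (!is.null(tip_order)) g0$tip_labels <- tip_order
    }
    gs[[l]] <- g0
  }
  # seed the divergence means from the data-driven split guesses
  if (is.null(init_params) && use_lik && nrow(model$div_edges)) {
    ths <- lapply(gs, attr, "tau_hat")
    for (e in seq_len(nrow(model$div_edges))) {
      dlab <- model$div_edges[e, 1]
      est <- stats::median(unlist(lapply(ths, `[`, dlab)), na.rm = TRUE)
      if (is.finite(est)) {
        nm <- paste0("tau_mean_", model$labels[dlab])
        s <- prior_support(priors$priors[[nm]])
        v[[nm]] <- min(max(est, s[1] + 0.001 * (s[2] - s[1])), 0.95 * s[2])
      }
    }
    params <- vector_to_params(v, model, b1 = b1)
  }
  pats <- if (use_lik) {
    lapply(data$alignments, compress_alignment, order = tip_order)
  }
  logf <- vapply(gs, genealogy_log_density, 1, params = params,
                 model = model)
  logL <- if (use_lik) {
    vapply(seq_len(nloci), function(l)
      pruning_loglike_pat(gs[[l]], pats[[l]], mut), 1)
  } else rep(0, nloci)
  ivs <- lapply(gs, genealogy_intervals, model = model)
  iv_all <- concat_intervals(ivs)
  lprior <- sum(vapply(pnames, function(nm)
    prior_logdens(v[[nm]], priors$priors[[nm]]), 1))

  wnd <- setNames(rep(0.5, length(pnames)), pnames)   # log-scale windows
  acc <- rej <- setNames(rep(0, length(pnames)), pnames)
  acc_win <- rej_win <- acc
  g_acc <- g_try <- 0
  n_div <- nrow(model$div_edges)
  wnd_shift <- vapply(seq_len(n_div), function(e)
    prior_support(priors$priors[[paste0(
      "tau_mean_", model$labels[model$div_edges[e, 1]])]])[2] / 10, 1)
  acc_shift <- rej_shift <- rep(0, n_div)

  keep <- floor((chain$iterations - chain$burnin) / chain$thin)
  samples <- matrix(NA_real_, keep, length(pnames),
                    dimnames = list(NULL, pnames))
  lp_trace <- numeric(keep)
  krow <- 0L

  for (it in seq_len(chain$iterations)) {
    ## parameter sweep
    for (nm in pnames) {
      pr <- priors$priors[[nm]]
      s <- prior_support(pr)
      x <- v[[nm]]
      y <- log(x) + runif(1, -wnd[[nm]], wnd[[nm]])
      # reflect into the prior support on the log scale; the triangle-wave
      # folding is an exactly symmetric proposal for any window width
      if (s[1] > 0 && is.finite(s[2])) {
        lb <- log(s[1]); ub <- log(s[2]); w <- ub - lb
        z <- (y - lb) %% (2 * w)
        y <- lb + if (z <= w) z else 2 * w - z
      } else if (is.finite(s[2])) {  # upper bound only
        ub <- log(s[2])
        if (y > ub) y <- 2 * ub - y
      }
      xn <- exp(y)
      v2 <- v; v2[[nm]] <- xn
      lp2 <- prior_logdens(xn, pr)
      if (!is.finite(lp2)) { rej[[nm]] <- rej[[nm]] + 1; next }
      params2 <- vector_to_params(v2, model, b1 = b1)
      lf2tot <- intervals_log_density(iv_all, params2, model)
      dl <- (lp2 - prior_logdens(x, pr)) + lf2tot - sum(logf) +
        (log(xn) - log(x))           # Jacobian of the log-scale walk
      if (is.finite(dl) && log(runif(1)) < dl) {
        v <- v2; params <- params2
        logf <- vapply(ivs, intervals_log_density, 1, params = params,
                       model = model)
        acc[[nm]] <- acc[[nm]] + 1; acc_win[[nm]] <- acc_win[[nm]] + 1
      } else {
        rej[[nm]] <- rej[[nm]] + 1; rej_win[[nm]] <- rej_win[[nm]] + 1
      }
    }
    ## joint divergence-shift move: translate the divergence mean together
    ## with every divergence event of that edge, so the mean and the event
    ## times can travel together instead of waiting for single-lineage
    ## re-simulations (translation has unit Jacobian and a symmetric
    ## proposal; moves that break branch containment or event order are
    ## rejected)
    for (e in seq_len(nrow(model$div_edges))) {
      nm <- paste0("tau_mean_", model$labels[model$div_edges[e, 1]])
      pr <- priors$priors[[nm]]
      sup <- prior_support(pr)
      delta <- runif(1, -wnd_shift[e], wnd_shift[e])
      xo <- v[[nm]]
      xn <- xo + delta
      if (xn <= max(sup[1], 0) || xn > sup[2]) {
        rej_shift[e] <- rej_shift[e] + 1
        next
      }
      gs2 <- shift_divergence_events(gs, model, e, delta)
      if (is.null(gs2)) { rej_shift[e] <- rej_shift[e] + 1; next }
      v2 <- v; v2[[nm]] <- xn
      params2 <- vector_to_params(v2, model, b1 = b1)
      ivs2 <- lapply(gs2, genealogy_intervals, model = model)
      logf2 <- vapply(ivs2, intervals_log_density, 1, params = params2,
                      model = model)
      dl <- (prior_logdens(xn, pr) - prior_logdens(xo, pr)) +
        sum(logf2) - sum(logf)
      if (is.finite(dl) && log(runif(1)) < dl) {
        v <- v2; params <- params2; gs <- gs2; ivs <- ivs2; logf <- logf2
        iv_all <- concat_intervals(ivs)
        acc_shift[e] <- acc_shift[e] + 1
      } else {
        rej_shift[e] <- rej_shift[e] + 1
      }
      if (it <= chain$burnin && (acc_shift[e] + rej_shift[e]) %% 50 == 0) {
        rate <- acc_shift[e] / (acc_shift[e] + rej_shift[e])
        if (rate < 0.2) wnd_shift[e] <- max(wnd_shift[e] * 0.7, sup[2] * 1e-4)
        if (rate > 0.4) wnd_shift[e] <- min(wnd_shift[e] * 1.4, sup[2])
      }
    }
    ## per-locus event-block translations at fixed parameters: move one
    ## locus's divergence events together (symmetric translation, unit
    ## Jacobian), which decouples the loci from the global shift move
    iv_dirty <- FALSE
    for (e in seq_len(nrow(model$div_edges))) {
      for (l in seq_len(nloci)) {
        delta <- runif(1, -wnd_shift[e], wnd_shift[e])
        g2 <- shift_divergence_events(gs[l], model, e, delta)
        if (is.null(g2)) next
        iv2 <- genealogy_intervals(g2[[1]], model)
        lf2 <- intervals_log_density(iv2, params, model)
        if (is.finite(lf2) && log(runif(1)) < lf2 - logf[l]) {
          gs[[l]] <- g2[[1]]
          ivs[[l]] <- iv2
          logf[l] <- lf2
          iv_dirty <- TRUE
        }
      }
    }
    ## genealogy moves
    for (k in seq_len(gu)) {
      l <- if (nloci > 1) sample.int(nloci, 1) else 1L
      prop <- propose_genealogy(gs[[l]], params, model)
      g_try <- g_try + 1
      if (!isTRUE(prop$ok)) next
      lf2 <- genealogy_log_density(prop$g, params, model)
      lL2 <- if (use_lik) pruning_loglike_pat(prop$g, pats[[l]], mut)
             else 0
      dl <- (lf2 + lL2) - (logf[l] + logL[l]) + prop$log_hastings
      if (is.finite(dl) && log(runif(1)) < dl) {
        gs[[l]] <- prop$g
        logf[l] <- lf2
        logL[l] <- lL2
        ivs[[l]] <- genealogy_intervals(prop$g, model)
        iv_dirty <- TRUE
        g_acc <- g_acc + 1
      }
    }
    if (iv_dirty) iv_all <- concat_intervals(ivs)
    ## window adaptation during burn-in, aiming for 20-40% acceptance
    if (it <= chain$burnin && it %% 50 == 0) {
      for (nm in pnames) {
        tot <- acc_win[[nm]] + rej_win[[nm]]
        if (tot >= 20) {
          rate <- acc_win[[nm]] / tot
          if (rate < 0.2) wnd[[nm]] <- max(wnd[[nm]] * 0.7, 1e-3)
          if (rate > 0.4) wnd[[nm]] <- min(wnd[[nm]] * 1.4, 10)
          acc_win[[nm]] <- rej_win[[nm]] <- 0
        }
      }
    }
    if (it > chain$burnin && (it - chain$burnin) %% chain$thin == 0 &&
        krow < keep) {
      krow <- krow + 1L
      samples[krow, ] <- v
      lp_trace[krow] <- sum(vapply(pnames, function(nm)
        prior_logdens(v[[nm]], priors$priors[[nm]]), 1)) +
        sum(logf) + sum(logL)
    }
    if (verbose && it %% 500 == 0) {
      message(sprintf("iter %d / %d, log kernel %.2f", it,
                      chain$iterations, sum(logf) + sum(logL)))
    }
  }
  samples <- as_tibble(samples[seq_len(krow), , drop = FALSE])
  smry <- summarize_posterior(samples, priors = priors, bins = chain$bins)
  structure(
    list(samples = samples, summary = smry, lp = lp_trace[seq_len(krow)],
         accept = tibble(parameter = pnames,
                         rate = unname(acc / pmax(acc + rej, 1)),
                         window = unname(wnd)),
         genealogy_accept = if (g_try) g_acc / g_try else NA_real_,
         genealogies = gs, model = model, priors = priors, chain = chain,
         b1 = b1, seed = chain$seed, used_likelihood = use_lik),
    class = "coaldiv_fit")
}

#' Summarize posterior samples with histograms
#'
#' For each parameter: an equal-width histogram over the prior support
#' (or the sample range when no prior is given), the mode as the midpoint
#' of the highest bin of the 3-bin moving-average smoothed histogram,
#' empirical 2.5% and 97.5% percentiles, and the standardized credibility
#' width `(p97.5 - p2.5) / mode`.
#'
#' @param samples data frame / tibble of posterior draws (columns =
#'   parameters), at least 100 rows.
#' @param priors optional [prior_spec()] fixing the histogram ranges.
#' @param bins number of histogram bins.
#' @return tibble with columns `parameter`, `mean`, `mode`, `p2.5`,
#'   `p97.5`, `std_width`, `ess`, `degenerate`.
#' @export
summarize_posterior <- function(samples, priors = NULL, bins = 1500L) {
  samples <- as.data.frame(samples)
  if (nrow(samples) < 100) {
    stop("need at least 100 retained samples to summarize")
  }
  rows <- lapply(names(samples), function(nm) {
    x <- samples[[nm]]
    degen <- isTRUE(sd(x) == 0)
    rng <- if (!is.null(priors) && nm %in% names(priors$priors)) {
      prior_support(priors$priors[[nm]])
    } else range(x)
    if (degen) {
      md <- x[1]
    } else {
      br <- seq(rng[1], rng[2], length.out = bins + 1L)
      h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), bins)
      sm <- stats::filter(h, rep(1 / 3, 3), sides = 2)
      sm[is.na(sm)] <- h[is.na(sm)]
      top <- which.max(sm)
      md <- (br[top] + br[top + 1L]) / 2
    }
    q <- unname(quantile(x, c(0.025, 0.975), names = FALSE))
    tibble(parameter = nm, mean = mean(x), mode = md,
           p2.5 = q[1], p97.5 = q[2],
           std_width = if (md > 0) (q[2] - q[1]) / md else
             if (q[2] == q[1]) 0 else Inf,
           ess = ess(x), degenerate = degen)
  })
  dplyr::bind_rows(rows)
}

#' @export
print.coaldiv_fit <- function(x, ...) {
  cat(sprintf(
    "coaldiv fit: %d retained samples, genealogy acceptance %.2f\n",
    nrow(x$samples), x$genealogy_accept))
  print(as.data.frame(x$summary[, c("parameter", "mode", "p2.5", "p97.5",
                                    "std_width", "ess")]), digits = 4)
  invisible(x)
}

#' @describeIn run_chain posterior summary table (broom-style).
#' @param x a `coaldiv_fit`.
#' @param ... unused.
#' @export
tidy.coaldiv_fit <- function(x, ...) x$summary

#' @describeIn run_chain one-row chain-level summary.
#' @export
glance.coaldiv_fit <- function(x, ...) {
  tibble(n_samples = nrow(x$samples),
         n_loci = length(x$genealogies),
         iterations = x$chain$iterations,
         burnin = x$chain$burnin,
         genealogy_accept = x$genealogy_accept,
         min_ess = min(x$summary$ess),
         seed = x$seed,
         used_likelihood = x$used_likelihood)
}

#' Plot posterior traces and histograms
#'
#' @param object a `coaldiv_fit`.
#' @param ... unused.
#' @return a ggplot object: one row per parameter with trace and marginal
#'   histogram.
#' @export
autoplot.coaldiv_fit <- function(object, ...) {
  s <- object$samples
  s$iteration <- seq_len(nrow(s))
  long <- tidyr_longer(s)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey35") +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = "parameter value", y = "posterior draws") +
    ggplot2::theme_minimal()
}

# minimal long-format pivot (avoids importing tidyr for one call)
tidyr_longer <- function(s) {
  nm <- setdiff(names(s), "iteration")
  dplyr::bind_rows(lapply(nm, function(p)
    tibble(iteration = s$iteration, parameter = p, value = s[[p]])))
}

#' @export
plot.coaldiv_fit <- function(x, ...) print(autoplot.coaldiv_fit(x))
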