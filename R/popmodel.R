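# Population models: which populations exist, how many samples each
# contributes, and which migration and divergence (label-switch) edges are
# legal. The connection structure is an adjacency matrix in the Migrate
# tradition; no guide tree is required, and several derived populations may
# share one ancestral population.

#' Declare a population model
#'
#' @param labels character vector of population names (ordered; user-facing
#'   population indices are 1-based in this order).
#' @param sample_counts non-negative integer vector of samples per
#'   population, recycled names from `labels` if unnamed.
#' @param adjacency optional n x n character matrix encoding the
#'   connections: entry `[j, i]` describes the edge from population `j`
#'   to population `i`; `"*"` = migration (forward-time migrants j to i;
#'   backward in time a lineage in `i` switches to `j` at rate `M[j,i]`),
#'   `"d"` = divergence (`j` derived, `i` ancestral), `"D"` = both,
#'   `"0"` = none. The diagonal is ignored. Alternatively supply
#'   `mig_edges` / `div_edges` directly.
#' @param mig_edges two-column integer matrix of migration edges
#'   `(source j, sink i)`.
#' @param div_edges two-column integer matrix of divergence edges
#'   `(derived, ancestral)`.
#' @return an object of class `pop_model`.
#' @examples
#' # population 2 splits from population 1 (1 is ancestral and present-day)
#' m <- pop_model(c("anc", "derived"), c(20, 20),
#'                div_edges = rbind(c(2, 1)))
#' validate_model(m)
#' @export
pop_model <- function(labels, sample_counts, adjacency = NULL,
                      mig_edges = NULL, div_edges = NULL) {
  stopifnot(is.character(labels), length(labels) >= 1,
            !anyDuplicated(labels))
  n <- length(labels)
  sample_counts <- as.integer(sample_counts)
  stopifnot(length(sample_counts) == n, all(sample_counts >= 0))
  names(sample_counts) <- labels

  if (!is.null(adjacency)) {
    stopifnot(is.matrix(adjacency), nrow(adjacency) == n,
              ncol(adjacency) == n)
    mig_edges <- div_edges <- matrix(integer(0), 0, 2)
    for (j in seq_len(n)) for (i in seq_len(n)) {
      if (i == j) next
      code <- adjacency[j, i]
      if (code %in% c("*", "D")) mig_edges <- rbind(mig_edges, c(j, i))
      if (code %in% c("d", "D")) div_edges <- rbind(div_edges, c(j, i))
      if (!code %in% c("*", "d", "D", "0", "-", "")) {
        stop("unknown adjacency code '", code, "' at [", j, ",", i, "]")
      }
    }
  }
  as_edges <- function(e) {
    if (is.null(e) || length(e) == 0) return(matrix(integer(0), 0, 2))
    e <- matrix(as.integer(e), ncol = 2)
    e
  }
  m <- structure(
    list(labels = labels, n_pop = n, sample_counts = sample_counts,
         mig_edges = as_edges(mig_edges), div_edges = as_edges(div_edges)),
    class = "pop_model")
  viol <- validate_model(m)
  if (length(viol)) stop("invalid population model:\n  ",
                         paste(viol, collapse = "\n  "))
  m
}

#' Validate a population model
#'
#' Checks every structural invariant and returns the violations as data
#' rather than raising: each divergence edge's derived population has
#' exactly one ancestral target, the divergence graph is acyclic, and all
#' edges reference declared populations.
#'
#' @param model a [pop_model()] (or an unchecked list with the same fields).
#' @return character vector of violation descriptions; empty when valid.
#' @export
validate_model <- function(model) {
  v <- character(0)
  n <- model$n_pop
  chk_ref <- function(e, what) {
    bad <- e[e < 1 | e > n]
    if (length(bad)) {
      sprintf("%s edge references undeclared population index %s",
              what, paste(unique(bad), collapse = ", "))
    } else character(0)
  }
  v <- c(v, chk_ref(model$mig_edges, "migration"),
         chk_ref(model$div_edges, "divergence"))
  de <- model$div_edges
  de <- de[de[, 1] >= 1 & de[, 1] <= n & de[, 2] >= 1 & de[, 2] <= n, ,
           drop = FALSE]
  if (nrow(de)) {
    if (anyDuplicated(de[, 1])) {
      dup <- unique(de[duplicated(de[, 1]), 1])
      v <- c(v, sprintf(
        "population %s has more than one ancestral divergence target",
        paste(model$labels[dup], collapse = ", ")))
    }
    if (any(de[, 1] == de[, 2])) {
      v <- c(v, "divergence edge from a population to itself")
    }
    # cycle check on the derived -> ancestral map
    anc <- rep(NA_integer_, n)
    anc[de[, 1]] <- de[, 2]
    for (s in unique(de[, 1])) {
      seen <- logical(n)
      p <- s
      while (!is.na(p) && !is.na(anc[p])) {
        if (seen[p]) {
          v <- c(v, sprintf("divergence edges form a cycle through %s",
                            model$labels[s]))
          break
        }
        seen[p] <- TRUE
        p <- anc[p]
      }
    }
  }
  if (any(model$mig_edges[, 1] == model$mig_edges[, 2])) {
    v <- c(v, "migration edge from a population to itself")
  }
  unique(v)
}

#' Legal backward-time transitions for a lineage
#'
#' For a lineage currently labeled `population`, lists the legal label
#' switches looking backward in time: immigration sources (the lineage's
#' label moves to the source of an incoming migration edge) and the
#' divergence target (the ancestral population, an irreversible switch).
#'
#' @param model a [pop_model()].
#' @param population a population label or 1-based index.
#' @return a tibble with columns `kind` (`"migration"` or `"divergence"`)
#'   and `target` (population label); zero rows for an isolated population.
#' @export
lineage_state_targets <- function(model, population) {
  i <- pop_index(model, population)
  mig <- model$mig_edges[model$mig_edges[, 2] == i, 1]
  div <- model$div_edges[model$div_edges[, 1] == i, 2]
  tibble(
    kind = c(rep("migration", length(mig)), rep("divergence", length(div))),
    target = model$labels[c(mig, div)]
  )
}

pop_index <- function(model, population) {
  if (is.character(population)) {
    i <- match(population, model$labels)
    if (is.na(i)) stop("unknown population label '", population, "'")
  } else {
    i <- as.integer(population)
    if (is.na(i) || i < 1 || i > model$n_pop) {
      stop("unknown population index ", population)
    }
  }
  i
}

#' @export
print.pop_model <- function(x, ...) {
  cat(sprintf("Population model: %d population(s)\n", x$n_pop))
  cat("  samples:", paste(sprintf("%s=%d", x$labels, x$sample_counts),
                          collapse = ", "), "\n")
  if (nrow(x$mig_edges)) {
    cat("  migration edges (source -> sink):",
        paste(sprintf("%s->%s", x$labels[x$mig_edges[, 1]],
                      x$labels[x$mig_edges[, 2]]), collapse = ", "), "\n")
  }
  if (nrow(x$div_edges)) {
    cat("  divergence edges (derived -> ancestral):",
        paste(sprintf("%s->%s", x$labels[x$div_edges[, 1]],
                      x$labels[x$div_edges[, 2]]), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Rate parameters for a population model
#'
#' Bundles all mutation-scaled rate parameters: per-population sizes
#' `Theta_i = 4 Ne_i mu`, per-migration-edge immigration rates
#' `M_ji = m_ji / mu`, and per-divergence-edge divergence-time
#' distributions (mean `tau_mean`, spread `tau_sd`, upper bound `b1`).
#'
#' @param model a [pop_model()].
#' @param theta numeric vector of mutation-scaled sizes, one per
#'   population (recycled if length 1); all `> 0`.
#' @param mig numeric vector of immigration rates, one per migration edge
#'   in `model$mig_edges` order (recycled if length 1); all `>= 0`.
#' @param tau_mean,tau_sd,b1 per-divergence-edge divergence distribution
#'   parameters (recycled if length 1); `tau_mean > 0`, `tau_sd > 0`,
#'   `b1 > tau_mean` or `Inf`.
#' @return an object of class `param_set`.
#' @export
param_set <- function(model, theta, mig = numeric(0), tau_mean = numeric(0),
                      tau_sd = numeric(0), b1 = Inf) {
  stopifnot(inherits(model, "pop_model"))
  n <- model$n_pop
  nm <- nrow(model$mig_edges)
  nd <- nrow(model$div_edges)
  theta <- rep_len(as.numeric(theta), n)
  stopifnot(all(theta > 0))
  if (nm > 0) {
    mig <- rep_len(as.numeric(mig), nm)
    stopifnot(all(mig >= 0))
  } else mig <- numeric(0)
  if (nd > 0) {
    tau_mean <- rep_len(as.numeric(tau_mean), nd)
    tau_sd <- rep_len(as.numeric(tau_sd), nd)
    b1 <- rep_len(as.numeric(b1), nd)
    stopifnot(all(tau_mean > 0), all(tau_sd > 0),
              all(b1 > tau_mean))
  } else tau_mean <- tau_sd <- b1 <- numeric(0)
  structure(list(theta = setNames(theta, model$labels), mig = mig,
                 tau_mean = tau_mean, tau_sd = tau_sd, b1 = b1),
            class = "param_set")
}

#' @export
print.param_set <- function(x, ...) {
  cat("Parameter set (mutation-scaled):\n")
  cat("  theta:", paste(sprintf("%s=%g", names(x$theta), x$theta),
                        collapse = ", "), "\n")
  if (length(x$mig)) cat("  M:", paste(signif(x$mig, 4), collapse = ", "), "\n")
  if (length(x$tau_mean)) {
    cat("  divergence:",
        paste(sprintf("mean=%g sd=%g b1=%g", x$tau_mean, x$tau_sd, x$b1),
              collapse = "; "), "\n")
  }
  invisible(x)
}

# div_dist for divergence edge e of the model
div_dist_of <- function(params, e) {
  div_dist(params$tau_mean[e], params$tau_sd[e], params$b1[e])
}

# n_pop vector: total incoming migration rate per sink population
incoming_mig_rate <- function(model, params) {
  out <- numeric(model$n_pop)
  if (nrow(model$mig_edges)) {
    for (r in seq_len(nrow(model$mig_edges))) {
      out[model$mig_edges[r, 2]] <- out[model$mig_edges[r, 2]] + params$mig[r]
    }
  }
  out
}
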