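# Sequence likelihood: F84 substitution model and Felsenstein pruning.
# Branch lengths are mutation-scaled (expected substitutions per site when
# the rate scalar is 1), matching the genealogy time scale, so the
# substitution process and the coalescent share one clock. Label-switch
# events on branches do not touch the substitution process.

BASES <- c("a", "c", "g", "t")
PURINE <- c(TRUE, FALSE, TRUE, FALSE)

#' F84 mutation model
#'
#' The Felsenstein 1984 model: unequal base frequencies plus one
#' transition/transversion parameter. Parameterized here by the expected
#' transition/transversion ratio; the rate matrix is normalized so one
#' time unit equals `rate` expected substitutions per site.
#'
#' @param freqs stationary base frequencies (A, C, G, T), positive, sum 1.
#' @param ts_tv expected transition/transversion ratio at stationarity;
#'   must exceed the ratio implied by a pure transversion process.
#' @param rate per-locus rate scalar (default 1).
#' @return an object of class `mutation_model` carrying the normalized
#'   rate matrix and its eigendecomposition.
#' @examples
#' mutation_model() # equal frequencies, ts/tv = 2
#' @export
mutation_model <- function(freqs = rep(0.25, 4), ts_tv = 2.0, rate = 1.0) {
  freqs <- as.numeric(freqs)
  if (length(freqs) != 4 || any(freqs <= 0) ||
      abs(sum(freqs) - 1) > 1e-8) {
    stop("base frequencies must be 4 positive numbers summing to 1")
  }
  stopifnot(rate > 0)
  piR <- freqs[1] + freqs[3]
  piY <- freqs[2] + freqs[4]
  pAG <- freqs[1] * freqs[3]
  pCT <- freqs[2] * freqs[4]
  # solve the within-group boost K from the requested ts/tv ratio
  kden <- pAG / piR + pCT / piY
  K <- (ts_tv * piR * piY - pAG - pCT) / kden
  if (K < 0) {
    stop("ts_tv ratio too small for these frequencies (implies K < 0)")
  }
  Q <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    boost <- if (PURINE[i] == PURINE[j]) {
      1 + K / if (PURINE[i]) piR else piY
    } else 1
    Q[i, j] <- freqs[j] * boost
  }
  diag(Q) <- -rowSums(Q)
  Q <- Q / sum(freqs * -diag(Q)) * rate   # mean rate = `rate`
  eig <- eigen(Q)
  structure(list(freqs = freqs, ts_tv = ts_tv, rate = rate, K = K, Q = Q,
                 evec = eig$vectors, eval = Re(eig$values),
                 ivec = solve(eig$vectors)),
            class = "mutation_model")
}

#' @export
print.mutation_model <- function(x, ...) {
  cat(sprintf("F84 model: freqs = (%s), ts/tv = %g, rate = %g\n",
              paste(signif(x$freqs, 4), collapse = ", "), x$ts_tv, x$rate))
  invisible(x)
}

#' F84 transition probability matrix
#'
#' `P(t) = exp(Q t)` for the model's normalized rate matrix; rows sum to 1,
#' `P(0)` is the identity, and `P(t)` converges to the stationary
#' frequencies as `t` grows.
#'
#' @param t branch length, `>= 0`, mutation-scaled.
#' @param m a [mutation_model()].
#' @return 4 x 4 stochastic matrix over (A, C, G, T).
#' @export
f84_transition_matrix <- function(t, m) {
  stopifnot(inherits(m, "mutation_model"))
  if (t < 0) stop("branch length must be >= 0")
  P <- Re(m$evec %*% (exp(m$eval * t) * m$ivec))
  P[P < 0] <- 0
  P / rowSums(P)
}

# character alignment -> per-tip partial likelihood arrays on unique site
# patterns. Non-ACGT symbols become fully ambiguous (1,1,1,1). The result
# (with per-tip partial matrices, ordered as `order`) is cached per locus
# by the MCMC driver, since the data never change within a run.
compress_alignment <- function(aln, order = rownames(aln)) {
  aln <- tolower(aln[order, , drop = FALSE])
  key <- apply(aln, 2, paste, collapse = "")
  tab <- table(key)
  patterns <- names(tab)
  weights <- as.numeric(tab)
  idx <- match(patterns, key)
  codes <- matrix(match(aln[, idx, drop = FALSE], BASES),
                  nrow(aln), length(idx))
  list(codes = codes, weights = weights,
       tip_partials = lapply(seq_len(nrow(codes)), function(v)
         tip_partial(codes[v, ])))
}

tip_partial <- function(codes_row) {
  np <- length(codes_row)
  L <- matrix(1, np, 4)
  known <- !is.na(codes_row)
  L[known, ] <- 0
  L[cbind(which(known), codes_row[known])] <- 1
  L
}

# unchecked F84 transition matrix kernel
.f84P <- function(t, m) {
  P <- Re(m$evec %*% (exp(m$eval * t) * m$ivec))
  P[P < 0] <- 0
  P / rowSums(P)
}

# pruning on a precomputed pattern object (tip order must match
# g$tip_labels, which compress_alignment(aln, g$tip_labels) guarantees)
pruning_loglike_pat <- function(g, pat, m) {
  np <- length(pat$weights)
  ntot <- 2L * g$n_tips - 1L
  part <- vector("list", ntot)
  part[seq_len(g$n_tips)] <- pat$tip_partials
  scaler <- numeric(np)
  ch <- children_of(g)
  ord <- setdiff(order(g$node_time), seq_len(g$n_tips))
  for (v in ord) {
    kids <- ch[[v]]
    P1 <- .f84P(g$node_time[v] - g$node_time[kids[1]], m)
    P2 <- .f84P(g$node_time[v] - g$node_time[kids[2]], m)
    L <- (part[[kids[1]]] %*% t(P1)) * (part[[kids[2]]] %*% t(P2))
    mx <- pmax(L[, 1], L[, 2], L[, 3], L[, 4], .Machine$double.xmin)
    scaler <- scaler + log(mx)
    part[[v]] <- L / mx
  }
  r <- root_node(g)
  site_l <- as.numeric(part[[r]] %*% m$freqs)
  sum(pat$weights * (log(site_l) + scaler))
}

#' Log likelihood of an alignment on a genealogy (Felsenstein pruning)
#'
#' Post-order pruning under the F84 model with site-pattern compression
#' and per-pattern rescaling. Gaps and ambiguity codes are treated as
#' missing (uniform partials). Migration and divergence events on the
#' genealogy are ignored: they relabel populations, not sequences.
#'
#' @param g an [event_genealogy()].
#' @param aln character matrix (tips x sites) with rownames matching the
#'   genealogy tip labels.
#' @param m a [mutation_model()].
#' @return log likelihood.
#' @export
pruning_loglike <- function(g, aln, m = mutation_model()) {
  stopifnot(inherits(g, "event_genealogy"), is.matrix(aln))
  if (is.null(rownames(aln)) || !setequal(rownames(aln), g$tip_labels)) {
    stop("alignment rownames must match the genealogy tip labels")
  }
  pruning_loglike_pat(g, compress_alignment(aln, g$tip_labels), m)
}
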