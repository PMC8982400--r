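# Numerical helpers shared across modules. All time arguments are
# mutation-scaled (expected substitutions per site) unless stated otherwise.

# log(exp(lx) - exp(ly)) for lx >= ly (unchecked), elementwise
logspace_sub <- function(lx, ly) {
  d <- ly - lx
  out <- lx + log1p(-exp(d))
  out[is.infinite(ly) & ly < 0] <- lx[is.infinite(ly) & ly < 0]
  out
}

# log(exp(lx) + exp(ly)), elementwise
logspace_add <- function(lx, ly) {
  m <- pmax(lx, ly)
  s <- pmin(lx, ly)
  out <- m + log1p(exp(s - m))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

#' Convert between mutation-scaled time and generations
#'
#' Internally all times are mutation-scaled (expected substitutions per
#' site). Figures and the literature often use `Ne` generations or `4 Ne`
#' generations. Given the mutation-scaled population size `theta = 4 Ne mu`
#' of the reference population, `x` units of `ne_units * Ne` generations
#' equal `x * ne_units * theta / 4` mutation-scaled time units.
#'
#' @param x times in generation units (multiples of `ne_units * Ne`).
#' @param theta mutation-scaled size of the reference population.
#' @param ne_units 1 for an `Ne`-generations axis, 4 for a
#'   `4 Ne`-generations axis.
#' @return mutation-scaled times.
#' @examples
#' gens_to_mut(1, theta = 0.01, ne_units = 4) # one 4Ne-generation unit
#' @export
gens_to_mut <- function(x, theta, ne_units = 1) {
  stopifnot(theta > 0, ne_units > 0)
  x * ne_units * theta / 4
}

#' @rdname gens_to_mut
#' @export
mut_to_gens <- function(x, theta, ne_units = 1) {
  stopifnot(theta > 0, ne_units > 0)
  x * 4 / (ne_units * theta)
}

# Effective sample size from the spectral density at frequency zero,
# estimated with an AR fit (same spirit as coda::effectiveSize).
ess <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 10 || var(x) == 0) return(0)
  fit <- tryCatch(ar(x, aic = TRUE, order.max = min(30, n %/% 4)),
                  error = function(e) NULL)
  if (is.null(fit) || length(fit$ar) == 0) return(n)
  s0 <- fit$var.pred / (1 - sum(fit$ar))^2
  max(0, min(n, n * var(x) / s0))
}
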