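# Truncated-normal divergence-time calculus.
#
# A lineage sampled in a derived population is at risk of switching its
# label to the ancestral population. The switching time follows a normal
# distribution with mean tau_mean and standard deviation tau_sd, truncated
# to [0, b1]. The instantaneous switching rate is the hazard of that
# distribution; because hazards condition on survival, the lower truncation
# at zero cancels and only the upper bound b1 enters.
#
# All tail quantities are evaluated through pnorm/qnorm in log space so that
# times far beyond tau_mean (up to tau_mean + 8 tau_sd and more) neither
# overflow nor cancel catastrophically.

#' Divergence-time distribution
#'
#' Describes the zero-truncated normal distribution of lineage
#' label-switching (divergence) times.
#'
#' @param tau_mean mean of the underlying normal, mutation-scaled time (> 0).
#' @param tau_sd standard deviation, mutation-scaled time (> 0).
#' @param b1 upper truncation bound; `Inf` (default) for no upper bound.
#' @return an object of class `div_dist`.
#' @examples
#' d <- div_dist(tau_mean = 0.005, tau_sd = 0.005)
#' div_hazard(0.005, d)
#' @export
div_dist <- function(tau_mean, tau_sd, b1 = Inf) {
  stopifnot(is.numeric(tau_mean), tau_mean > 0,
            is.numeric(tau_sd), tau_sd > 0,
            is.numeric(b1), b1 > 0)
  structure(list(tau_mean = tau_mean, tau_sd = tau_sd, b1 = b1),
            class = "div_dist")
}

#' @export
print.div_dist <- function(x, ...) {
  cat(sprintf("Divergence-time distribution: N(%g, %g) truncated to [0, %g]\n",
              x$tau_mean, x$tau_sd, x$b1))
  invisible(x)
}

# log of P(t < X < b1) for X ~ N(tau_mean, tau_sd), vectorized over t.
# .lum and friends are unchecked kernels shared with the simulation and
# MCMC hot paths; the exported wrappers validate their arguments.
.lum <- function(t, tm, sd, b1) {
  lt <- pnorm(t, tm, sd, lower.tail = FALSE, log.p = TRUE)
  if (is.finite(b1)) {
    lb <- pnorm(b1, tm, sd, lower.tail = FALSE, log.p = TRUE)
    logspace_sub(lt, rep(lb, length(lt)))
  } else {
    lt
  }
}

.haz <- function(t, tm, sd, b1) {
  exp(dnorm(t, tm, sd, log = TRUE) - .lum(t, tm, sd, b1))
}

.cumhaz <- function(t0, u, tm, sd, b1) {
  out <- .lum(t0, tm, sd, b1) - .lum(t0 + u, tm, sd, b1)
  out[u == 0] <- 0
  out
}

.sampdiv <- function(t0, r, tm, sd, b1, n_risk = 1) {
  lt <- log1p(-r) / n_risk + .lum(t0, tm, sd, b1)
  if (is.finite(b1)) {
    lb <- pnorm(b1, tm, sd, lower.tail = FALSE, log.p = TRUE)
    lt <- logspace_add(lt, rep(lb, length(lt)))
  }
  pmax(qnorm(lt, tm, sd, lower.tail = FALSE, log.p = TRUE) - t0, 0)
}

log_upper_mass <- function(t, d) .lum(t, d$tau_mean, d$tau_sd, d$b1)

#' Divergence hazard rate
#'
#' Instantaneous rate at which a derived lineage switches to its ancestral
#' label at time `t`: the hazard `f(t) / (1 - F(t))` of the truncated
#' normal divergence-time distribution. The zero lower bound cancels out of
#' the hazard; the upper bound `b1` does not.
#'
#' @param t time (mutation-scaled), `0 <= t < b1`; vectorized.
#' @param d a [div_dist()].
#' @return hazard rate(s), finite for `t < b1`.
#' @export
div_hazard <- function(t, d) {
  stopifnot(inherits(d, "div_dist"))
  if (any(t < 0) || any(t >= d$b1)) {
    stop("div_hazard is defined on [0, b1); got t outside the support")
  }
  exp(dnorm(t, d$tau_mean, d$tau_sd, log = TRUE) - log_upper_mass(t, d))
}

#' Cumulative divergence hazard
#'
#' Integral of [div_hazard()] over `[t0, t0 + u]`, in closed form as the log
#' ratio of normal upper-tail masses. Additive in abutting intervals and
#' equal to the numerical integral of the hazard.
#'
#' @param t0 interval start time, `>= 0`; vectorized.
#' @param u interval length, `>= 0`, with `t0 + u <= b1`; vectorized.
#' @inheritParams div_hazard
#' @return cumulative hazard(s), `>= 0`; `Inf` when `t0 + u == b1`.
#' @export
div_cum_hazard <- function(t0, u, d) {
  stopifnot(inherits(d, "div_dist"))
  if (any(t0 < 0) || any(u < 0) || any(t0 + u > d$b1)) {
    stop("div_cum_hazard needs 0 <= t0 <= t0 + u <= b1")
  }
  out <- log_upper_mass(t0, d) - log_upper_mass(t0 + u, d)
  out[u == 0] <- 0
  out
}

#' Divergence waiting-time density
#'
#' Density of the waiting time `u` until a derived lineage switches labels,
#' given that it has not switched by `t0`:
#' `exp(-Lambda(t0, t0+u)) * hazard(t0 + u)`.
#'
#' @inheritParams div_cum_hazard
#' @param log return the log density?
#' @return density value(s); integrates to 1 over `u` in `[0, b1 - t0)`.
#' @export
div_waiting_density <- function(t0, u, d, log = FALSE) {
  ld <- dnorm(t0 + u, d$tau_mean, d$tau_sd, log = TRUE) - log_upper_mass(t0, d)
  if (log) ld else exp(ld)
}

#' Inverse-transform draw of a divergence waiting time
#'
#' Solves `exp(-Lambda(t0, t0 + u)) = 1 - r` for `u`: the survival-function
#' inversion that turns a uniform variate into a waiting time of the
#' time-inhomogeneous divergence process started at `t0`. Solved through
#' `qnorm` on log-scale tail masses, so the round trip
#' `div_cum_hazard(t0, u, d) == -log(1 - r)` holds to near machine
#' precision even deep in the tail.
#'
#' @inheritParams div_hazard
#' @param t0 conditioning time (lineage has not switched by `t0`), `t0 < b1`.
#' @param r uniform variate(s) in `(0, 1]`.
#' @param n_risk number of independent at-risk lineages sharing the hazard;
#'   the returned `u` is then the waiting time to the first switch among
#'   them (survival `exp(-n_risk * Lambda)`).
#' @return waiting time(s) `u > 0`; `r = 1` gives `b1 - t0` (or `Inf`).
#' @export
sample_div_time <- function(t0, r, d, n_risk = 1) {
  stopifnot(inherits(d, "div_dist"), n_risk >= 1)
  if (any(t0 < 0) || any(t0 >= d$b1)) stop("need 0 <= t0 < b1")
  if (any(r <= 0) || any(r > 1)) stop("r must be in (0, 1]")
  # target log upper mass at t0 + u:
  # log[(b1 mass at t0+u)] = log(1 - r)/n_risk + log[(b1 mass at t0)]
  .sampdiv(t0, r, d$tau_mean, d$tau_sd, d$b1, n_risk)
}

# upper integration limit beyond which exp(-Lambda) is numerically zero
div_support_end <- function(t0, d, k = 12) {
  min(d$b1, max(d$tau_mean, t0) + k * d$tau_sd)
}

#' Exact first-event probabilities by quadrature
#'
#' In an interval starting at `t0`, a lineage configuration experiences a
#' constant total coalescence + migration rate `lam_cm` in competition with
#' the time-varying divergence hazard. `xi_divergence_exact` is the
#' probability that the divergence event comes first,
#' `integral of exp(-u lam_cm) * hazard(t0+u) * exp(-Lambda(t0, t0+u)) du`.
#' The survival factor times the hazard equals the truncated-normal density
#' renormalized by the mass above `t0`, which is what is integrated.
#'
#' @param lam_cm total constant competing rate (coalescence + migration),
#'   `>= 0`.
#' @param d a [div_dist()].
#' @param t0 interval start time.
#' @param n_risk number of at-risk derived lineages sharing the hazard.
#' @param rel.tol quadrature relative tolerance.
#' @return a probability in `[0, 1]`. Quadrature failure to converge is an
#'   error reporting the achieved tolerance.
#' @export
xi_divergence_exact <- function(lam_cm, d, t0 = 0, n_risk = 1,
                                rel.tol = 1e-10) {
  stopifnot(inherits(d, "div_dist"), lam_cm >= 0, t0 >= 0, t0 < d$b1)
  up <- div_support_end(t0, d) - t0
  f <- function(u) {
    h <- n_risk * div_hazard(pmin(t0 + u, d$b1 * (1 - 1e-12)), d)
    exp(-u * lam_cm - n_risk * div_cum_hazard(rep(t0, length(u)), u, d)) * h
  }
  q <- tryCatch(
    integrate(f, 0, up, rel.tol = rel.tol, abs.tol = 1e-12,
              subdivisions = 500L),
    error = function(e) stop("quadrature for xi_d failed: ",
                             conditionMessage(e))
  )
  if (q$message != "OK") {
    stop("quadrature for xi_d did not converge (abs.error = ",
         format(q$abs.error), ")")
  }
  min(max(q$value, 0), 1)
}

#' @rdname xi_divergence_exact
#' @param lam_event constant rate of the focal event class (for
#'   `xi_constant_exact`, e.g. the total coalescence rate when computing
#'   `xi_c`).
#' @export
xi_constant_exact <- function(lam_event, lam_cm, d, t0 = 0, n_risk = 1,
                              rel.tol = 1e-10) {
  stopifnot(lam_event >= 0, lam_event <= lam_cm)
  if (lam_event == 0) return(0)
  up <- div_support_end(t0, d) - t0
  f <- function(u) {
    lam_event *
      exp(-u * lam_cm - n_risk * div_cum_hazard(rep(t0, length(u)), u, d))
  }
  q <- integrate(f, 0, up, rel.tol = rel.tol, abs.tol = 1e-12,
                 subdivisions = 500L)
  # tail beyond `up`: survival is numerically zero there unless lam_cm
  # dominates and b1 = Inf never lets the hazard explode -- the normal
  # hazard grows without bound, so exp(-Lambda) at `up` is < 1e-30.
  min(max(q$value, 0), 1)
}

#' Midpoint approximation of the divergence first-event probability
#'
#' Replaces the time-varying divergence hazard by its value at a fixed
#' point `t0 + eps`, turning the first-event probability into the simple
#' competing-exponential ratio `lam_d_eps / (lam_cm + lam_d_eps)`.
#'
#' @param lam_cm total constant competing rate, `>= 0`.
#' @param lam_d_eps divergence hazard evaluated at the chosen `t0 + eps`,
#'   `>= 0`. Not both rates may be zero.
#' @return a probability in `[0, 1]`; the three event-class ratios sum to
#'   one exactly.
#' @export
xi_divergence_approx <- function(lam_cm, lam_d_eps) {
  stopifnot(lam_cm >= 0, lam_d_eps >= 0)
  if (lam_cm + lam_d_eps == 0) stop("both competing rates are zero")
  lam_d_eps / (lam_cm + lam_d_eps)
}

#' @rdname xi_divergence_approx
#' @param d a [div_dist()].
#' @param t0 interval start time.
#' @param eps evaluation offset for the hazard. The default `"auto"` uses
#'   the fixed point `eps = 1 / (lam_cm + hazard(t0 + eps))`, i.e. the
#'   expected waiting time implied by the approximation itself; inside a
#'   genealogy, where the realized interval length `u` is known, pass
#'   `eps = u`.
#' @param n_risk number of at-risk derived lineages.
#' @export
xi_divergence_approx_at <- function(lam_cm, d, t0 = 0, eps = "auto",
                                    n_risk = 1) {
  stopifnot(inherits(d, "div_dist"))
  cap <- div_support_end(t0, d, k = 8)
  if (identical(eps, "auto")) {
    h <- n_risk * div_hazard(min(t0, cap), d)
    for (i in seq_len(50)) {
      e <- 1 / (lam_cm + h)
      h_new <- n_risk * div_hazard(min(t0 + e, cap), d)
      if (abs(h_new - h) < 1e-12 * (1 + h)) { h <- h_new; break }
      h <- h_new
    }
  } else {
    stopifnot(is.numeric(eps), eps >= 0)
    h <- n_risk * div_hazard(min(t0 + eps, cap), d)
  }
  xi_divergence_approx(lam_cm, h)
}
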