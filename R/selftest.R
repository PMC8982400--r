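# Fast built-in invariant checks, callable from the CLI (`coaldiv
# selftest`) or interactively after installation.

#' Run the fast invariant self-test suite
#'
#' Checks, in a few seconds: the closed-form cumulative divergence hazard
#' against numerical quadrature of the hazard; the competing-risks
#' normalization of the exact first-event probabilities; the survival
#' inversion round trip; the Kingman closed form for single-population
#' genealogies; and that prior draws match the prior distribution.
#'
#' @param seed integer seed (the report is identical across runs with the
#'   same seed).
#' @param verbose print a pass/fail line per check.
#' @param .corrupt_cum_hazard internal test hook: perturb the cumulative
#'   hazard inside the quadrature check so that its failure mode is
#'   exercised.
#' @return tibble with columns `check`, `pass`, `detail`.
#' @export
selftest <- function(seed = 1L, verbose = TRUE,
                     .corrupt_cum_hazard = FALSE) {
  set.seed(seed)
  out <- list()
  rec <- function(check, pass, detail) {
    out[[length(out) + 1L]] <<- tibble(check = check, pass = pass,
                                       detail = detail)
  }

  # cumulative hazard closed form vs quadrature
  worst <- 0
  for (i in 1:20) {
    tm <- 10^runif(1, -3, -1.3)
    d <- div_dist(tm, tm * 10^runif(1, -1, 0.5))
    t0 <- runif(1, 0, tm)
    u <- runif(1, 0, tm)
    num <- integrate(function(x) div_hazard(x, d), t0, t0 + u,
                     rel.tol = 1e-11)$value
    cf <- div_cum_hazard(t0, u, d) + if (.corrupt_cum_hazard) 1e-3 else 0
    worst <- max(worst, abs(cf - num) / max(num, 1e-12))
  }
  rec("cumulative hazard: closed form vs quadrature", worst < 1e-7,
      sprintf("max rel err %.2e", worst))

  # competing-risks normalization
  worst <- 0
  for (i in 1:10) {
    d <- div_dist(10^runif(1, -3, -1.5), 10^runif(1, -3.5, -1.5))
    lc <- 10^runif(1, 0, 3); lm <- 10^runif(1, 0, 3)
    tot <- xi_constant_exact(lc, lc + lm, d) +
      xi_constant_exact(lm, lc + lm, d) +
      xi_divergence_exact(lc + lm, d)
    worst <- max(worst, abs(tot - 1))
  }
  rec("first-event probabilities sum to one", worst < 1e-6,
      sprintf("max |sum - 1| = %.2e", worst))

  # survival inversion round trip
  d <- div_dist(0.005, 0.002)
  t0 <- runif(200, 0, 0.006)
  r <- runif(200)
  u <- sample_div_time(t0, r, d)
  err <- max(abs(exp(-div_cum_hazard(t0, u, d)) - (1 - r)))
  rec("divergence-time draw inverts the survival function", err < 1e-8,
      sprintf("max round-trip err %.2e", err))

  # Kingman closed form on simulated trees
  m1 <- pop_model("A", 5)
  p1 <- param_set(m1, theta = 0.02)
  worst <- 0
  for (i in 1:25) {
    g <- simulate_genealogy(m1, p1)
    ts <- sort(g$node_time[-(1:5)])
    ks <- 5:2
    closed <- sum(log(2 / 0.02) -
                    coalescent_rate(ks, 0.02) * diff(c(0, ts)))
    worst <- max(worst, abs(genealogy_log_density(g, p1, m1) - closed))
  }
  rec("single-population density matches the Kingman closed form",
      worst < 1e-8, sprintf("max abs log err %.2e", worst))

  # prior draws match the prior cdf
  pr <- list(dist = "exponential", mean = 0.01, upper = 0.05)
  x <- prior_draw(pr, 4000)
  ks <- suppressWarnings(stats::ks.test(
    x, function(q) pexp(q, 100) / pexp(0.05, 100))$statistic)
  rec("prior sampler matches the prior distribution", ks < 0.05,
      sprintf("KS distance %.3f", ks))

  res <- dplyr::bind_rows(out)
  if (verbose) {
    for (i in seq_len(nrow(res))) {
      cat(sprintf("[%s] %s (%s)\n",
                  if (res$pass[i]) "ok" else "FAIL",
                  res$check[i], res$detail[i]))
    }
  }
  invisible(res)
}

#' Plot a lineage-survival curve
#'
#' @param df output of [lineage_survival_fraction()].
#' @return a ggplot object.
#' @export
plot_lineage_survival <- function(df) {
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tau,
                                   y = .data$frac_surviving)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "candidate split time (mutation-scaled)",
                  y = "fraction of replicates with >= 2 lineages") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
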