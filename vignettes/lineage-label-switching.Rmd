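---
title: "Divergence-time inference with lineage label switching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Divergence-time inference with lineage label switching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coaldiv)
```

## The model

Classical isolation-with-migration (IM) inference treats the divergence
time between two populations as a sharp boundary: below it, a structured
coalescent with migration; above it, a single ancestral population.
`coaldiv` implements a different device. Looking backward in time, every
sampled lineage of a derived population is *at risk* of irreversibly
switching its population label to the ancestral label. The switching time
of each lineage is a random draw governed by the hazard function of a
normal distribution with mean `tau_mean` and standard deviation `tau_sd`,
truncated to `[0, b1]`:

$$\lambda_d(t) \;=\; \frac{\phi_{\mu,\sigma}(t)}
 {\Phi_{\mu,\sigma}(b_1) - \Phi_{\mu,\sigma}(t)},$$

where $\phi$ and $\Phi$ are the normal density and distribution function.
The lower truncation at zero cancels out of the hazard. Because a hazard
integrates into a cumulative hazard
$\Lambda(t_0, t_0+u) = \log\frac{\Phi(b_1)-\Phi(t_0)}{\Phi(b_1)-\Phi(t_0+u)}$
with survival $e^{-\Lambda}$, label switching slots directly into the
structured-coalescent machinery, where coalescence (rate $k(k-1)/\Theta$)
and immigration (rate $M$ per lineage) already produce exponential
waiting times. The divergence boundary becomes fuzzy: its position is
`tau_mean` and its sharpness is `tau_sd`. As `tau_sd` shrinks the model
converges to the classical IM model with a hard split.

All times and rates are **mutation-scaled**: one time unit is one
expected substitution per site, $\Theta_i = 4 N_i \mu$, and
$M_{ji} = m_{ji}/\mu$. The product $\Theta_{\text{deme}} \times M$ is the
familiar $4Nm$, the number of immigrant gene copies per generation.
Figures in the population-genetic literature often use axes in $N_e$ or
$4 N_e$ generations; `gens_to_mut()` and `mut_to_gens()` convert, with
$x$ units of $4N_e$ generations equal to $x\,\Theta$ mutation-scaled
time. The two axis conventions differ by a factor of four and are easy
to confuse; every function in this package states its units.

A population model (`pop_model()`) declares the populations, their
sample counts, and the legal connections — migration edges and
divergence edges — via an adjacency matrix; no guide tree is needed, and
several derived populations may share one ancestral population (for
example two islands colonized independently from a mainland). Population
indices are 1-based in all user-facing interfaces.

## First-event probabilities

Within a genealogy interval starting at $t_0$, the probability that a
divergence event precedes all coalescences and migrations is

$$\xi_d = \int_0^\infty e^{-u\lambda_{c+m}}\,
  \lambda_d(t_0+u)\, e^{-\Lambda(t_0,t_0+u)}\, du ,$$

which has no closed form. `xi_divergence_exact()` evaluates it by
adaptive quadrature (absolute tolerance $10^{-10}$, integrating to
$\min(b_1, \max(\mu,t_0) + 12\sigma)$, beyond which the survival factor
is numerically zero). A fast approximation replaces the time-varying
hazard by its value at a fixed offset $\epsilon$, giving the familiar
competing-exponentials ratio
$\xi_d \approx \lambda_d(t_0+\epsilon) / (\lambda_{c+m} +
\lambda_d(t_0+\epsilon))$ (`xi_divergence_approx()`). Inside a genealogy
the realized interval length $u$ is known and is used as $\epsilon$. For
the standalone comparison no $u$ exists; `xi_divergence_approx_at()`
defaults to the self-consistent fixed point
$\epsilon = 1/(\lambda_{c+m} + \lambda_d(t_0+\epsilon))$ — the expected
waiting time implied by the approximation itself — which tracks the
quadrature result to within about 0.02 across three decades of
$\Theta$, $M$ and `tau_mean`; the package tests assert agreement within
0.05.

## Genealogy density

An `event_genealogy` is an ultrametric binary tree whose branches carry
time-stamped label-switch events. Its probability density given the
rates is a product over the global time intervals delimited by every
coalescence and event. Each interval contributes the survival of all
competing risks — $e^{-u\lambda_{c+m}}$ for the constant rates and one
cumulative hazard $e^{-\Lambda}$ per at-risk derived lineage — times the
rate of the specific event that ends it: $2/\Theta_i$ for the observed
coalescing pair, $M_{ji}$ for the observed migration, $\lambda_d(t)$ for
the observed label switch. We deliberately use this *labeled* convention
for all three event classes. A convention that multiplies the divergence
factor by the number of at-risk lineages $k$ counts unlabeled outcomes
("some lineage switched") and is the exact analogue of writing
$k(k-1)/\Theta$ instead of $2/\Theta$ for a specific coalescing pair;
mixing the two conventions breaks the identity between the density and
the generative simulation. With the labeled convention the density
factorizes exactly as iid hazard draws per lineage, the two-tip density
integrates to one, and the simulator, the proposal kernel and the
density agree — properties the test suite checks explicitly.

The density is accumulated in log space throughout: thousand-locus
products and deep-tail survival factors underflow otherwise. Tail
quantities go through `pnorm`/`qnorm` with `log.p = TRUE`, so hazards
and inversions stay accurate at least eight standard deviations past the
mean.

## Simulation

`simulate_genealogy()` runs the backward process by competing draws: at
each step a waiting time is proposed for every possible event class —
exponential for coalescence and migration, survival inversion
$u = \Lambda^{-1}(-\log(1-r))$ (`sample_div_time()`, solved through
`qnorm` in log space) for divergence — and the earliest is applied. The
inversion for the first switch among $k$ at-risk lineages divides the
log-survival target by $k$, which is exact for iid hazards. Simulation
stops at the sample's most recent common ancestor: events on the single
root lineage have total probability one and do not affect the density.

Two divergence modes exist because they differ subtly:
`mode = "hazard"` (the default, and the model the sampler targets) draws
an independent switching time per lineage; `mode = "epoch"` draws a
single zero-truncated normal epoch per divergence edge
(`draw_divergence_epoch()`, rejection sampling of non-positive draws)
and switches every derived lineage at that shared moment — a hard split
at a random time, matching the convention of standard coalescent
simulators when `tau_sd` is small. In epoch mode, migration edges
touching a derived population are shut off above its epoch; in hazard
mode migration edges stay active at all times, because a lineage that
immigrates into a derived label deep in the past is immediately pushed
out again by the then-enormous hazard — the model needs no special case.

The lineage-survival experiment (`lineage_survival_fraction()`) asks how
often a sample still has two or more uncoalesced lineages at a candidate
split time under migration: once a sample has coalesced to a single
lineage, nothing older leaves a trace in the data. Because the
below-split dynamics do not depend on where the split is placed, one set
of count-level replicates (no tree construction) yields the whole
survival curve.

## Likelihood and mutation model

Sequence likelihoods use Felsenstein pruning under the F84 model:
stationary base frequencies plus one transition/transversion parameter,
rate matrix normalized so branch lengths are expected substitutions per
site — the same clock as the coalescent. Transition matrices come from
the eigendecomposition of the rate matrix, computed once per parameter
set. Site patterns are compressed and per-pattern rescaling guards
against underflow on large trees. Ambiguity codes and gaps become
uniform partials. Label-switch events never touch the substitution
process, so adding migration events to a branch leaves the likelihood
unchanged — an invariant the tests exercise. Site-rate heterogeneity and
richer substitution models are out of scope.

## The sampler

`run_chain()` samples parameters and per-locus genealogies by
Metropolis–Hastings. Its moves:

* **Parameter slides.** Each scalar parameter takes a sliding-window
  step on the log scale, reflected into the prior support by
  triangle-wave folding (exactly symmetric for any window width — naive
  single reflection is *not* symmetric once the adapted window exceeds
  the support width, a bias we caught with prior-recovery tests).
  The $x' / x$ Jacobian of the log walk enters the acceptance ratio.
  Windows adapt during burn-in toward 20–40% acceptance. Parameter moves
  only touch the genealogy-density term, which is re-priced from cached
  interval decompositions of all loci in one vectorized pass.
* **Lineage re-simulation.** `propose_genealogy()` detaches the branch
  above one random non-root node and re-simulates that lineage backward
  with the competing-draws scheme against the fixed remainder, until it
  re-coalesces. Past the old root, the remaining root lineage joins the
  process (it can migrate and diverge too), so label mismatches resolve
  instead of deadlocking; symmetrically, when the detached lineage
  starts above the remainder's root, the root lineage's own path from
  its node up to the start is re-simulated as well. The acceptance
  ratio uses explicitly computed proposal densities in both directions —
  no cancellation between target and proposal is assumed, which keeps
  the kernel exact even where the moving unit is a subtree whose fixed
  lineages interact with the re-simulated path. A safety cap (10,000
  steps) turns runaway proposals into rejections.
* **Divergence shifts.** The divergence mean moves *together with every
  switch event of its edge* by a common offset (unit Jacobian, symmetric
  proposal; moves that would push an event off its branch or reorder a
  branch's events are rejected). Per-locus translations of one locus's
  event block at fixed parameters complement the global shift. Without
  these, the mean and the events wait for each other and the chain can
  take thousands of sweeps to traverse a few hundred time units.

Priors are uniform (bounds) or truncated exponential (mean and upper
bound) per parameter class. The upper truncation bound $b_1$ of the
divergence distribution defaults to three times the divergence-mean
prior's upper bound. Posterior summaries use equal-width histograms over
the prior support (1,500 bins by default), the mode as the midpoint of
the highest bin after 3-bin moving-average smoothing, empirical 2.5% and
97.5% percentiles, and the standardized credibility width
$(p_{97.5} - p_{2.5})/\text{mode}$ as the spread summary. Effective
sample sizes come from an AR-fit spectral estimate; they are reported,
not hidden — short chains on hard targets are visibly short.

Starting values matter for short chains. With data, each locus starts
from a UPGMA tree on Jukes–Cantor distances, labeled as a hard split at
a data-driven guess (0.9 times the 5% quantile of cross-population pair
heights — cross-population coalescences cannot predate the split), and
the divergence-mean start is seeded from the same guess. A chain started
in the wrong labeling basin (for example, all lineages switching
immediately) can take very long to escape; the prior-process fallback
start is used only when the data-informed start is unavailable.

## What the generator emulates, and what it does not

The synthetic-data path reproduces the study conditions of the method's
evaluation: two populations of 20 sampled lineages each with combined
$\Theta = 0.02$, loci of 1,000 bp under F84 (equal frequencies,
transition/transversion ratio 2 — the evaluation did not fix these, so
defaults are stated here), divergence times spanning fractions to
multiples of $N_e$ generations, and IM settings with $4Nm$ of 0.25 or
1.0. Hazard mode generates data from the inference model itself; epoch
mode with small `tau_sd` mimics classical hard-split simulators. Real
data differ in ways the generator does not emulate: recombination within
loci, site-rate heterogeneity, base-composition bias, sequencing error,
serial sampling, and population-size change over time. Passing the
package's tests therefore demonstrates correctness of the implementation
under its own model, not robustness to those violations.

The package's own checks run at desk scale on one core, deliberately
smaller than a cluster study: the parameter-recovery experiment uses 10
samples per population, 10 loci of 1,000 bp, three true split times
(0.125, 0.5 and 1.0 $N_e$ generations, i.e. mutation-scaled 0.0003125,
0.00125 and 0.0025), hard-split (epoch) data, and chains of 4,000
sweeps — sizes chosen so the full suite runs in tens of minutes while
still separating the three truths. The credibility-width comparison runs
matched 2-locus and 10-locus datasets at the two larger split times and
asserts only the ordering of the mean standardized widths; the
mode-standardized width is numerically unstable when the posterior mode
approaches zero (as it does at the smallest split time, where dividing
by a near-zero mode inflates the statistic arbitrarily), and full-scale
averages require hundreds of replicates. The lineage-survival experiment runs 1,000
replicates per split time, as in the original design.

## Numerical choices and edge cases

* Quadratures: cumulative-hazard identities are validated against
  `integrate()` at relative tolerance $10^{-8}$ or better; the
  first-event integrals use absolute tolerance $10^{-12}$.
* The survival form of the first-event integrand is
  $e^{-\Lambda}$ (a decaying factor); the hazard times survival equals
  the truncated-normal density renormalized by the mass above $t_0$,
  which is the form actually integrated.
* Degenerate inputs: `u = 0` intervals contribute exactly zero
  cumulative hazard; `tau_sd = 0` epoch draws return the mean exactly;
  constant posterior samples yield width zero and a `degenerate` flag.
* Ties: branch event lists must be strictly increasing in time; the
  epoch mode records simultaneous switches on *different* branches,
  which is legal.
* A divergence edge whose derived population still has lineages at
  $t \ge b_1$ has density $-\infty$; the sampler never proposes such
  states because the inversion respects the bound.

## Limitations

Single-chain, single-temperature MCMC: no heating or parallel
tempering, so hard multimodal targets (very high migration plus old
splits) mix slowly; effective sample sizes in the output are the honest
diagnostic. Tip-dated (ancient) samples, recombination, marginal-
likelihood model comparison, and automatic exploration of alternative
population trees are out of scope; alternative population models are
separate runs. The proposal step cap and the desk-scale chain lengths
are pragmatic bounds, reported as such in the fit object.
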