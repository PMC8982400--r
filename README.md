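# coaldiv

Bayesian estimation of population divergence times in which the
divergence is not a sharp boundary but an assembly of per-lineage
label-switching events, embedded in the structured coalescent with
migration.

## The problem and the model

Isolation-with-migration (IM) methods date the split of two populations
while allowing gene flow after the split. They usually treat the split
time as a hard boundary between two models: a structured coalescent with
migration below it, one panmictic ancestral population above it.
`coaldiv` instead treats the split as a random variable per lineage.
Looking backward in time, each sampled lineage of a derived population is
at risk of irreversibly switching its population label to the ancestral
label; the switching time follows the hazard of a normal distribution
with mean τ and standard deviation σ, truncated to [0, b₁]:

    λ_d(t) = φ(t; τ, σ) / (Φ(b₁; τ, σ) − Φ(t; τ, σ))

Coalescence (rate k(k−1)/Θ for k lineages in a population of
mutation-scaled size Θ = 4Nμ) and immigration (mutation-scaled rate
M = m/μ per lineage) keep their usual exponential waiting times, and the
time-varying divergence hazard integrates into the same framework via its
cumulative hazard Λ with survival e^(−Λ). The genealogy density is a
product over the time intervals delimited by all events; the posterior of
(Θ, M, τ, σ) is sampled by Metropolis–Hastings over parameters and
event-augmented genealogies, with sequence likelihoods from Felsenstein
pruning under the F84 mutation model. The package targets population
geneticists who want divergence times with honest uncertainty, including
the σ of the divergence itself, and who may have many loci.

All internal times are mutation-scaled (expected substitutions per site);
`gens_to_mut()` / `mut_to_gens()` convert to the Nₑ- or 4Nₑ-generation
axes common in the literature.

What it provides:

* the truncated-normal divergence calculus: hazard, cumulative hazard,
  waiting density, inverse-transform sampling, and first-event
  probabilities both by quadrature and by the fast midpoint ratio;
* backward-in-time simulation of event genealogies and F84 sequence data
  (per-lineage hazard mode and shared-epoch hard-split mode);
* the genealogy probability density and pruning likelihoods;
* the MCMC sampler with histogram posterior summaries
  (mode, 2.5%/97.5% percentiles, standardized credibility width);
* the lineage-survival experiment quantifying when old splits are
  unknowable under migration;
* PHYLIP/FASTA input, an event-annotated Newick dialect, a plain-text
  model-file format, and a thin command-line tool
  (`inst/exec/coaldiv`) with `simulate`, `infer`, `survival` and
  `selftest` subcommands.

## A worked example

Simulate ten 1,000-bp loci for 10 + 10 samples under a hard split of the
derived population at τ = 0.00125 (half an Nₑ generation; Θ = 0.01 per
population), then re-infer:

```r
library(coaldiv)

model <- pop_model(c("anc", "der"), c(10, 10), div_edges = rbind(c(2, 1)))
truth <- param_set(model, theta = 0.01, tau_mean = 0.00125,
                   tau_sd = 0.00125 / 1e4)
data <- simulate_dataset(model, truth, loci = 10, sites = 1000,
                         mode = "epoch", seed = 302)

priors <- prior_spec(model,
  theta    = list(dist = "uniform", min = 1e-4, max = 0.1),
  tau_mean = list(dist = "exponential", mean = 0.0025, upper = 0.0075),
  tau_sd   = list(dist = "uniform", min = 1e-6, max = 0.001))

fit <- run_chain(data, model, priors,
                 chain_config(iterations = 4000, burnin = 1333,
                              thin = 2, seed = 302,
                              genealogy_updates = 10))
tidy(fit)
#> # A tibble: 4 × 8
#>   parameter        mean     mode     p2.5    p97.5 std_width   ess degenerate
#>   <chr>           <dbl>    <dbl>    <dbl>    <dbl>     <dbl> <dbl> <lgl>
#> 1 theta_anc    0.00971  0.00886  0.00767  0.0121       0.495  26.7 FALSE
#> 2 theta_der    0.00988  0.00912  0.00714  0.0132       0.665 169.  FALSE
#> 3 tau_mean_der 0.00143  0.00143  0.00119  0.00162      0.300  17.9 FALSE
#> 4 tau_sd_der   0.000551 0.000519 0.000418 0.000773     0.682  33.8 FALSE
```

Both population sizes are recovered near their true 0.01, and the true
split time 0.00125 lies inside the 95% credible interval
[0.00119, 0.00162] with posterior mode 0.00143. `std_width` is the
standardized credibility width (p97.5 − p2.5)/mode; `ess` is the
effective sample size of the retained draws — short desk-scale chains
are visibly short, and longer runs tighten these. `glance(fit)` gives
chain-level diagnostics and `autoplot(fit)` the marginal histograms.

How often is an old split knowable at all? Under symmetric migration at
4Nm = 1, count the replicates that still have two or more uncoalesced
lineages at the candidate split (the survival fractions below are from
`seed = 7`, 1,000 replicates, 20 + 20 samples, Θ = 0.01 per deme):

```r
island <- pop_model(c("A", "B"), c(20, 20),
                    mig_edges = rbind(c(1, 2), c(2, 1)))
pars <- param_set(island, theta = 0.01, mig = 100)   # Theta * M = 4Nm = 1
lineage_survival_fraction(island, pars,
  tau_grid = gens_to_mut(c(1, 2, 4), theta = 0.01, ne_units = 4),
  reps = 1000, seed = 7)
#> # A tibble: 3 × 3
#>     tau frac_surviving  reps
#>   <dbl>          <dbl> <dbl>
#> 1  0.01          0.934  1000
#> 2  0.02          0.532  1000
#> 3  0.04          0.101  1000
```

By a split four 4Nₑ-generation units back, only ~10% of samples retain
any information about it — splits older than that are estimated mostly
from the prior no matter how many loci are sequenced.

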