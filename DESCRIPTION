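Package: coaldiv
Title: Bayesian Population Divergence Times via Lineage Label Switching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Divergence-time inference for structured populations in which
    each sampled lineage switches its population label from "derived" to
    "ancestral" at a time drawn from the hazard function of a zero-truncated
    normal distribution, embedded in the structured coalescent with
    migration. Provides the truncated-normal hazard calculus (hazard,
    cumulative hazard, waiting-time density, inverse-transform sampling,
    first-event probabilities with exact quadrature and a midpoint
    approximation), backward-in-time simulation of event-augmented
    genealogies and F84 sequence data, the genealogy probability density,
    Felsenstein pruning likelihoods, and Metropolis-Hastings sampling of
    genealogies and parameters (mutation-scaled population sizes,
    immigration rates, divergence-time mean and spread) with histogram
    posterior summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    ape
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
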