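Package: conceive
Title: Bayesian Modelling of Time to Pregnancy from Cycles of Non-Conception
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Numerical Bayesian analysis of time to pregnancy under a
    beta-geometric fecundability model. A couple's latent per-cycle chance
    of conception (the intrinsic conception rate) is described by a prior
    distribution mixing a point mass of sterility with continuous beta or
    triangular components. The package computes the survival function of
    non-conception, the posterior distribution of the intrinsic conception
    rate after any number of unsuccessful cycles, clinically relevant
    fertility metrics (sterile proportion, posterior percentiles,
    probability of conceiving within the next k cycles), and the number of
    cycles before chosen subfertility thresholds are crossed. An extension
    models female reproductive ageing with couple-specific sterility ages
    and a linear fertility decline, and a seedable Monte-Carlo cohort
    simulator provides an independent stochastic cross-check.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
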