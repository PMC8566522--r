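Package: hamr
Title: Mediation Analysis of the Home Advantage in Paired Match Data
Version: 0.1.0
Authors@R:
    person("Analytics", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how the home advantage in association
    football arises and how it changes when matches are played without
    spectators. Provides a generator for paired home/away match tables with
    a known structural model, latent construct scoring (team performance,
    refereeing decisions, outcome) by single-factor analysis, a hierarchical
    Bayesian moderated-mediation path model with team-within-league random
    intercepts (own Gibbs sampler, with an lme4 cluster-bootstrap
    alternative), effect decomposition into direct, indirect and total
    effects with credible intervals, descriptive home-advantage summaries,
    leave-one-league-out and home-minus-away robustness harnesses, and a
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    lme4,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
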