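Package: palaeotrait
Title: Macroevolution of Body Size on Fossil Time-Trees
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Phylogenetic comparative analysis of continuous-trait
    macroevolution on non-ultrametric, fossil-rich time-calibrated
    phylogenies. Implements maximum-likelihood fitting and AICc ranking of
    eleven trait-evolution models (Brownian motion, Ornstein-Uhlenbeck,
    directional trend, early burst, Pagel's kappa, Levy-type pulsed
    evolution, environment-coupled OU with curve-dependent optima, and
    multi-peak OU on painted regime histories), discrete-habitat model
    selection by reversible-jump MCMC over Mk rate structures, stochastic
    character mapping by uniformization, state-dependent
    lineage-through-time summaries, ancestral-state reconstruction with
    convergent-origin counting, phylogenetic regression, permutational
    ANOVA on ecospace occupancy, and predator/prey tallying. Includes a
    synthetic-data generator (fossilized birth-death trees, trait and
    habitat histories, environmental curves, community tables) so the full
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Rcpp,
    jsonlite,
    lhs,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    Matrix,
    nlme,
    optparse,
    phytools,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
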