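Package: banditmsm
Title: Bandit-Driven Adaptive Sampling and Markov State Model Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Adaptive sampling campaigns for stochastic dynamical systems
    driven by a UCB1 multi-armed bandit acquisition function whose reward is
    minus the Markov-state-model free energy of the visited states, together
    with the analysis stack needed to resolve kinetics from the sampled data:
    trajectory discretization by mini-batch k-means, reversible and
    non-reversible Markov state model estimation, time-lagged independent
    component analysis, PCCA-style metastable coarse-graining, transition
    path theory (committors, reactive fluxes, macrostate flux networks and
    observable-conditioned flux decomposition), and binding kinetics
    (mean first passage times, association/dissociation rates and binding
    free energies with trajectory-bootstrap uncertainty). Ships overdamped
    Langevin and discrete Markov chain toy engines with exact equilibrium
    and kinetic ground truth for validating every estimator end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
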