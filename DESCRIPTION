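Package: ssfir
Title: Behavioural-Response SIR Epidemics on Complex Networks
Version: 1.0.0
Authors@R:
    person("Ming", "Delaunay", email = "m.delaunay@example.org", role = c("aut", "cre"))
Description: Tools for the SSFIR epidemic model, a susceptible-infected-recovered
    process on networks extended with a self-protective susceptible class: when a
    susceptible node contacts an infectious neighbour it may become infected at
    rate beta or adopt protective behaviour at rate beta_F, after which it is
    infected at the discounted rate gamma*beta. The package provides an exact
    event-driven (Gillespie) stochastic simulator on arbitrary networks, random
    graph generators (Erdos-Renyi, uncorrelated configuration model with a
    sqrt(N) degree cutoff), a bond-percolation / cavity solution for the epidemic
    threshold and the final prevalence based on degree generating functions, the
    variability-measure protocol for locating the threshold from ensembles of
    stochastic runs, and the degree-based mean-field ODE system whose threshold
    prediction the other two engines contradict. A small command-line driver
    reproduces the figure-level experiments from configuration files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
SystemRequirements: C++17
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
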