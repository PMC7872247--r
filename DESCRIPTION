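Package: massdyn
Title: Mass-Action Kinetic Modeling and Ensemble Simulation of Metabolic
    Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construct mass-action kinetic models of metabolic networks from
    stoichiometry and equilibrium constants, parameterize them from
    steady-state flux and concentration data via pseudo-elementary rate
    constants (PERCs), sample thermodynamically feasible concentration and
    flux states with hit-and-run Markov chain Monte Carlo, expand net
    enzymatic reactions into mechanistic enzyme modules with elementary
    binding and catalysis steps, and run an ensemble workflow that
    assembles candidate models from sampled states, filters them by
    dynamic stability, simulates the survivors, and aggregates ensemble
    statistics such as the adenylate energy charge. Models import and
    export through a JSON schema and export to SBML Level 3 core.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    boot,
    deSolve,
    jsonlite,
    pracma,
    stats,
    utils,
    xml2
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    yaml
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
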