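Package: feastfamine
Title: Generalist and Specialist Population Dynamics Under Feast-Famine Cycles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates microbial population dynamics under stochastic
    feast-famine cycles in which discrete nutrient pulses alternate with
    starvation. Phenotypes are constrained by a resource-use trade-off that
    fixes the geometric mean of their growth rates across nutrient
    environments, and by a growth-death trade-off that links fast growth
    during feast to fast death during famine. Provides exact event-driven
    integration of the piecewise-linear dynamics, construction of discrete
    and quasi-continuous phenotype spaces with phenotypic switching,
    coarse-grained invasion analysis (growth-to-death ratio criterion,
    dominance transition, strategy-branching point), interval-statistics
    theory for sparse nutrient supply, and orchestration of parameter scans
    over the mean and variance of the supply interval.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
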