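Package: selfcell
Title: From Flux Balance Analysis to Self-Contained Cellular Growth Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Constraint-based modelling of small metabolic networks with an
    emphasis on mass conservation and thermodynamic consistency.  Provides
    stoichiometric linear algebra (mass-conservation auditing, null spaces,
    elementary flux modes), flux balance analysis under multiple objectives
    with Pareto fronts, thermodynamic constraints (loop laws, loopless
    MILP, sign-vector cycle tests, concentration coupling, max-min driving
    force), enzyme-capacity and enzyme-cost formulations, macromolecular
    unit growth models where the specific growth rate follows from the
    molecular weights and the flux vector, reversible enzyme kinetics with
    Haldane-consistent parameterisation, and a self-contained
    resource-allocation growth optimiser in which fluxes are evaluated
    through kinetic rate laws.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    pracma
Config/testthat/edition: 3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'network_core.R'
    'efm.R'
    'macro_units.R'
    'model_io.R'
    'kinetics.R'
    'fixtures.R'
    'selfcontained.R'
    'lp.R'
    'fba.R'
    'enzyme.R'
    'thermo.R'
    'cli.R'
RoxygenNote: 7.3.3
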