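Package: LTCproj
Title: Multi-State Markov Projection of Elderly Disability and Long-Term Care Costs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing disability levels in elderly populations and
    projecting the size and long-term care cost of the disabled-elderly
    population. Implements a four-dimension weighted disability score with
    banded severity classification, estimation of multi-year disability-state
    transition matrices from panel data, annualization of multi-year matrices
    by a step-size transform with error-driven calibration, queue-element
    (cohort-component) projection of state counts under mortality, new
    entrants and scenario drift, and per-capita long-term care cost
    accounting. Includes a synthetic-data generator and an agent-based
    microsimulation oracle so the full pipeline is testable without access to
    restricted survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'LTCproj-package.R'
    'cdae.R'
    'cost.R'
    'pipeline.R'
    'projection.R'
    'synthetic.R'
    'transition.R'
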