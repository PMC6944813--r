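Package: casckit
Title: Care Cascade Modelling, Scenario Analysis and Budget Optimization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Expresses a care cascade (continuum of care) as a discrete-time
    compartmental model defined by declarative framework, databook and program
    book tables; projects cascade stages over time; layers intervention
    programs on top via linear unit-cost coverage functions, coverage-blended
    parameter effects and screening-style conversion-flow chains; runs budget
    scenarios against a baseline projection; and optimizes budget allocations
    against cascade objectives (maximize a stage, minimize losses, minimize
    funding for a target) under per-program and total-budget constraints using
    an adaptive stochastic descent solver with a feasibility projection.
    Includes demonstration projects (a hypertension care cascade and a generic
    testing/treatment cascade) and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    optparse,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
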