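Package: bsfgrow
Title: Dynamic Growth and Development Modelling of Black Soldier Fly Larvae
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and fits a two-state dynamic model of black soldier fly
    (Hermetia illucens) larval rearing: dry mass driven by regulated ingestion,
    assimilation and maturity-maintenance fluxes, and a development sum that
    generalizes degree-days to multiple environmental factors. Includes thermal
    performance curves (Arrhenius with boundary corrections, modified Logan-10),
    Monod feed- and airflow-limitation kinetics, piecewise moisture responses
    with logistic smoothing, ODE simulation over time-varying environment
    schedules with stage-event detection, seeded synthetic-data generators, and
    a multi-start bounded nonlinear least-squares estimation workflow with
    dataset normalization, grouping and subset recalibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
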