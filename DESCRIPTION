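Package: ltcproj
Title: Illness-Death Model Projections of Long-Term Care Demand
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Projects the age- and sex-specific prevalence and the absolute
    number of people in need of long-term care with a three-state
    illness-death model. The transport partial differential equation linking
    prevalence, incidence and state-specific mortality is integrated along
    age-period characteristics with a classical fourth-order Runge-Kutta
    scheme; the inverse problem (incidence from prevalence, all-cause
    mortality and a mortality rate ratio) is solved by algebraic
    rearrangement of the same equation. Includes an eight-scenario
    projection engine (two population variants, two mortality rate ratios,
    with and without a secular incidence trend), head-count and care-ratio
    reporting, long-format CSV readers and writers, a command-line
    interface, and a mechanistic generator of demographic test fixtures
    (logistic baseline prevalence, Gompertz mortality with secular
    improvement, cohort-consistent population pyramids).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    deSolve
Config/testthat/edition: 3
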