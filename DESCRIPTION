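Package: retkin
Title: Compartmental Analysis of Whole-Body Retinol Kinetics in Neonatal Rats
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation and weighted nonlinear fitting of an
    eight-compartment linear tracer model of whole-body vitamin A (retinol)
    kinetics in neonatal rats, including transport delays for chylomicron
    production and metabolism, a piecewise-constant ("time interrupt") loss
    coefficient, and a time-varying uptake coefficient describing the
    transient perturbation caused by vitamin A/retinoic acid (VARA)
    supplementation. Provides the derived kinetic calculus (transit and
    residence times, recycling numbers, fractional catabolic and disposal
    rates, traced masses and transfer rates), nested-model comparison by
    F-statistic and AIC, between-group coefficient tests, sensitivity
    analysis of fixed absorption coefficients, and a synthetic pup-level
    study generator emulating the oral tritiated-retinol dosing design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
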