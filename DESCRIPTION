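Package: itcbind
Title: Equilibrium Binding Substates from Calorimetric Titrations and
    Single-Transporter Uptake Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Forward modelling and nonlinear fitting of isothermal titration
    calorimetry (ITC) isotherms under single-state and two-state independent
    binding models, including competitive displacement titrations, dilution
    heat correction, multistart fitting with identifiability scans, model
    comparison, and conversion of fitted substate populations into a closed
    thermodynamic-cycle free-energy ledger. Also provides global shared-rate
    multi-exponential fitting of single-transporter uptake time courses with
    modal (fast/intermediate/slow) kinetic populations, and seeded synthetic
    data generators for both data types.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    minpack.lm,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
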