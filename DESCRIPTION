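Package: aortafsi
Title: Reduced-Order Biomechanics of the Ascending Aorta
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Patient-specific reduced-order modelling of ascending aortic
    biomechanics. Implements an anisotropic modified Mooney-Rivlin
    constitutive model for the aortic wall, a semi-analytic incompressible
    thick-walled inflation solver, a quasi-1D pulsatile flow model in the
    compliant vessel, the inverse procedures used to personalise such models
    (preshrink to the zero-load configuration, stiffness-ratio calibration to
    CT lumen volumes, outlet-pressure calibration to Doppler inlet velocity),
    a two-sample cohort inference protocol (Shapiro-Wilk, Brown-Forsythe
    Levene, Student/Welch t-tests), a packaged 20-patient Tetralogy of Fallot
    cohort with per-patient hemodynamic metrics, and a seeded synthetic
    cohort generator for end-to-end validation by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    car,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
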