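Package: tracegtt
Title: Tracer-Based Oral Glucose and Mixed-Meal Tolerance Test Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for stable-isotope ([U-13C6] glucose) tracer
    oral glucose and mixed-meal tolerance tests in mice. Corrects GC-MS
    mass-isotopologue distributions for natural isotope abundance by
    multiple linear regression, fits a two-compartment oral absorption
    model to the labelled-glucose time course (apparent absorption
    constant ka, plasma clearance k2, bioavailability F), reconstructs
    endogenous glucose production EGP(t) from the unlabelled glucose pool,
    fits the biexponential insulin response, and computes tissue-specific
    (peripheral IS-P, hepatic IS-L) and whole-body (HOMA-IR, Matsuda)
    insulin-sensitivity indices. Includes a seeded virtual-mouse cohort
    simulator with known ground truth for validation, dam-as-experimental-
    unit group statistics (one-way ANOVA with Tukey HSD, type-II two-way
    sex-by-group ANOVA), and an end-to-end cohort report pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    minpack.lm,
    pracma,
    car,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
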