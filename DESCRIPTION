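Package: idrflex
Title: Conformational Flexibility Analysis of Intrinsically Disordered Protein Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for studying the conformational flexibility of
    intrinsically disordered protein regions and its modulation by point
    mutation and partner binding. Provides composition-based disorder scoring
    with exhaustive disorder-to-order substitution scanning, far-UV circular
    dichroism spectral arithmetic (blanking, mean residue ellipticity and
    molar extinction conversions, replicate averaging, non-interacting
    expectation and partner-induced difference spectra, co-solvent dilution
    planning), secondary-structure deconvolution by simplex-constrained ridge
    least squares against a reference basis, two-wavelength conformational
    classification, microscale-thermophoresis binding-affinity estimation with
    a depletion-aware 1:1 mass-action model and saturation diagnostics, and
    seeded synthetic-data generators so that every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    seqinr,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
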