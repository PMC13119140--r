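Package: pedddi
Title: Pediatric Extrapolation of CYP-Mediated Drug-Drug Interaction AUC
    Ratios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Static-model prediction of cytochrome P450 (CYP)-mediated
    drug-drug interaction magnitude in children from adult data.  The
    adult AUC ratio of a victim drug is extrapolated to a pediatric age
    by correcting the fraction of clearance through the affected CYP for
    enzyme ontogeny (Emax-type maturation functions for CYP1A2, CYP2B6,
    CYP2C9, CYP2C19 and CYP3A4/5) and for body size (allometric scaling
    of total clearance with the Luscombe weight-for-age formula).  Ships
    a 25-case pediatric validation dataset of victim-perpetrator pairs
    with observed and published predicted AUC ratios, plus the standard
    prediction-performance metrics (geometric mean fold error, mean
    absolute prediction error, two-fold and Guest acceptance limits,
    ordinary least-squares calibration).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
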