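Package: ribopk
Title: Translational Pharmacokinetics of mRNA-Encoded Antibodies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for predicting human pharmacokinetics of antibodies
    expressed in vivo from intravenously administered mRNA lipid
    nanoparticles (mRNA-LNPs). Implements noncompartmental analysis of
    concentration-time profiles (linear-up/log-down AUC, terminal slope
    selection, dose-normalized exposure metrics), interspecies allometric
    scaling of dose-normalized Cmax and AUC with a generalized-exponent
    grid search, and a mechanistic translational model coupling first-order
    mRNA-LNP elimination and non-consumptive translation to two-compartment
    antibody disposition, with body-weight power-law scaling of every
    parameter. Model parameters are estimated from multispecies data by
    pooled maximum likelihood with proportional residual error, and fitted
    single-species parameters are projected to human for first-in-human
    exposure prediction with fold-error reporting. A synthetic-study
    generator reproduces the statistical structure of multispecies
    IV-infusion studies (log-normal between-subject variability,
    proportional residual error) so every analysis is runnable without
    external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
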