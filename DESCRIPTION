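Package: nanotoxtracker
Title: Dose-Response Modelling and Dose-Metric Identification for
    Nanoparticle Reporter Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for ToxTracker-style nanoparticle screens in
    GFP reporter cell lines. Fits fixed-slope Hill cytotoxicity curves to
    estimate LD50 and equi-response doses, converts mass concentrations of
    spherical particles to particle-number and surface-area concentrations,
    identifies the dose metric governing toxicity across a particle size
    series from the slope of the log-log equi-response line (surface area -2,
    volume -3, particle number 0), and calls GFP reporter activation from
    autofluorescence-corrected fold induction with viability gating. Includes
    a synthetic-data generator emulating the statistical structure of
    flow-cytometry well summaries so every stage is testable without
    proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown,
    ggplot2
Config/testthat/edition: 3
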