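Package: vlcea
Title: Cost and Impact Modelling of Plasma and Dried-Specimen HIV Viral Load Scale-up
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A deterministic cost-outcomes model for national scale-up of HIV
    viral load (VL) monitoring when laboratory networks can collect plasma,
    dried blood spot (DBS), or plasma separation card (PSC) specimens.
    Implements a facility-stratified access model, a misclassification-aware
    testing cascade (sensitivity/specificity at the 1000 copies/mL threshold,
    confirmatory repeat testing, failure-prevalence calibration), component
    costing, incremental cost-effectiveness with strict and extended dominance,
    and one-way/two-way deterministic sensitivity analysis with break-even
    (threshold) price solving. Ships a calibrated synthetic Zambia facility
    network and the published base-case inputs, and a generator for synthetic
    facility panels emulating geospatial transport-network model output.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
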