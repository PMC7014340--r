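Package: phoscade
Title: Export-Coefficient Modelling of Phosphorus Loads and Lake Status in
    Standing-Water Catchments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Predicts annual total-phosphorus (TP) loads and in-lake TP
    concentrations for networks of standing-water sub-catchments using a
    land-cover and slope export-coefficient model, per-capita waste-water and
    septic-tank loads, additive point sources (fish farms, birds, atmospheric
    deposition), an annual water balance, cascading routing through the
    drainage network, and the OECD/Vollenweider load-to-concentration model
    with separate shallow-lake and combined parameterisations.  Modelled
    concentrations are classified against Water Framework Directive (WFD)
    class-boundary breakpoints and trophic-state thresholds, with a
    red-amber-green proximity indicator and headroom (assimilative capacity)
    estimates.  Includes a scenario mode (land-cover transfer, climate
    scaling, population and point-source changes), one-at-a-time sensitivity
    drivers for export coefficients and discharge, a seeded synthetic
    catchment-network generator, and calibrated single-lake case-study
    fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
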