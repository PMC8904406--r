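Package: hoofprint
Title: Water and Land Footprint Accounting for Livestock Production Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Accounting of green and blue water footprints and grazing/cropland
    land footprints of ruminant milk and meat production, disaggregated by
    animal category, production system (arid, semi-arid, humid) and
    socio-economic scenario over 2005-2040. Computes per-animal feed dry-matter
    demand from feed conversion ratios and per-animal product output, allocates
    it across feed baskets, converts it to water and land footprints, and
    derives water and land productivity (kg product per cubic metre and per
    hectare) together with herd-level aggregates. Includes a compound-growth
    scenario projection layer and a seeded synthetic-data generator that
    emulates economic-model outputs so the full pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
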