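Package: ichno
Title: Ichnological Suitability Mapping by Weighted Multi-Criteria Overlay
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Palaeontological predictive modelling of ichnofossil (trace fossil)
    suitability for crater-lake landscapes. Converts a bedrock geology map, an
    optional surficial-deposit map and a digital elevation model into ordinal
    factor-score rasters (substrate, energy, sedimentation rate, water table,
    surficial cover), aggregates them by weighted linear combination with a
    surficial-cover penalty into bioturbation, bioerosion and biostratification
    suitability maps, classifies them at a configurable threshold, and extracts
    ranked high-suitability sites with per-site ichnofossil-type and
    detection-mode recommendations. Includes a seeded synthetic crater-landscape
    generator so the whole pipeline is testable without external data, and a
    small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
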