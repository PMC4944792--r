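Package: coastvuln
Title: Coastal Drinking-Water Vulnerability Index Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Assessment of coastal drinking-water vulnerability on a
    half-degree coastal grid. Six ordinal classifiers score exposure
    (cyclone landfall incidence, elevation, geomorphology), sensitivity
    (population density) and resilience (September rainfall, groundwater
    salinity) on a 1-3 scale; the scores are combined into a Coastal
    Vulnerability Index (CVI) as the square root of their product mean and
    classified with fixed limits. Includes cyclone-track landfall detection
    with a two-degree impact footprint, 2050/2100 climate-change scenario
    re-projection, exposure summaries (coastline length and population per
    vulnerability class), and a seeded synthetic-world generator with known
    ground truth for end-to-end testing.
License: MIT
Encoding: UTF-8
Imports:
    geosphere,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
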