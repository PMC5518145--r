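Package: gridpsu
Title: Primary Sampling Unit Selection from Gridded Population Data
Version: 0.1.0
Authors@R: person("Analysis", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Selects primary sampling units (PSUs) for complex household
    surveys directly from gridded population rasters instead of census
    enumeration areas. Seed cells are drawn by stratified serpentine
    systematic sampling with probability proportionate to estimated
    population size (PPES), optionally adjusted so urban/rural sub-domains
    reach a minimum household sample and so every coarse spatial grid cell
    holds a PSU, then grown into contiguous PSUs by randomized dilation
    within per-seed Voronoi regions until a population target or area cap
    is met. Includes Horvitz-Thompson style household and individual
    design-weight calculators, a seeded synthetic-fixture generator, and
    plain-text raster (ESRI ASCII grid) and GeoJSON input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
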