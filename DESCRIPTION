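Package: coastbc
Title: Coastal Blue Carbon Habitat Mapping and Landscape Pressure Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping coastal blue carbon habitats (seagrass, other
    rooted submerged macrophytes, open and forested wetlands) on a regular
    grid and for scoring their exposure to land-based human activities.
    Includes delimitation of the coastal analysis domain from an elevation
    model (low-lying land hydrologically connected to the sea, minus lakes
    and road-severed enclaves, plus the submerged mapping-feasibility area),
    compilation of habitat classes from land-cover, multi-year submerged
    aquatic vegetation and modelled seagrass layers, a three-component
    distance- and area-based pressure index with cumulative impact scoring,
    protected-area overlap accounting, field-point quality control, and a
    synthetic landscape generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
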