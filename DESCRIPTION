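Package: halven
Title: Coupled Carbon and Biodiversity Assessment of Nitrogen-Fertilizer Reduction Scenarios
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale pipeline assessing a 50% nitrogen-fertilizer-reduction policy for
    EU-like agricultural landscapes. Generates gridded Baseline and Halving-N land-use
    scenario pairs for two economic archetypes (land abandonment and crop extensification),
    crosswalks economic land-use categories to biodiversity land-use/intensity classes and
    land-surface-model plant functional types, projects species richness, total abundance,
    compositional similarity and the Biodiversity Intactness Index relative to primary
    vegetation, accounts ecosystem carbon (NPP, soil and biomass carbon) with regional
    aggregation and a serial-correlation-corrected significance test, decomposes indicator
    differences into area and intensity effects with the logarithmic mean Divisia index,
    and classifies grid cells into Win/Loss quadrants.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
Config/testthat/edition: 3
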