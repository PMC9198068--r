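Package: pdindex
Title: Physical Distancing Index from Clustered Household Survey Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs a household-level physical distancing index (PDI) from
    five private-infrastructure deprivation indicators (shared sanitation,
    public water source, crowding, no mobile phone, no vehicle) via the first
    principal component of the standardized indicator matrix; aggregates
    household scores to subnational regions with survey sample weights and an
    optional log(1 + population density) weight; min-max normalizes the index;
    estimates smooth pixel-level index surfaces with penalized tensor-product
    B-splines; and validates regional indices against epidemic caseloads and
    against known synthetic truth. Ships a generator for DHS-like clustered
    survey microdata (spatially correlated latent deprivation, displaced
    cluster coordinates, sample weights, density rasters, regional caseloads)
    so the full pipeline is testable without restricted survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    mgcv,
    splines,
    stats,
    tools,
    utils
Suggests:
    geosphere,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
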