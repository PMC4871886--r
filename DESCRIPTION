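Package: micrograze
Title: Microcosm Grazing Experiments: Ingestion Rates, Carbon Conversions,
    and Microbial Community Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of bottle-incubation grazing experiments
    with gelatinous predators (jellyfish ephyrae) feeding on natural
    microplankton assemblages. Infers per-predator clearance and ingestion
    rates from control versus treatment bottle counts under the exponential
    growth/grazing model, converts cell biovolumes to carbon biomass with
    allometric equations, converts radiotracer and fluorogenic-substrate
    assay signals into heterotrophic carbon production and aminopeptidase
    activity rates, and profiles OTU community composition with rarefaction,
    Bray-Curtis similarity, group-average (UPGMA) clustering, permutation
    ANOSIM and exact Mann-Whitney tests. A synthetic-data generator with the
    statistical structure of the microcosm design supports end-to-end tests
    and parameter-recovery experiments without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
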