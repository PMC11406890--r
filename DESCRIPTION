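Package: weanflux
Title: Community Flux Balance Screening of Food-Breastmilk Diets for the
    Infant Gut Microbiome
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Abundance-weighted community flux balance analysis with a
    cooperative growth trade-off, driven by diet flux vectors built from
    food composition tables. Assembles genus pan-reconstructions into a
    block stoichiometric community model, completes the diet medium so
    every taxon reaches a floor growth rate, and screens food-breastmilk
    combinations for their predicted effect on short-chain and
    branched-chain fatty acid production relative to a milk-only control.
    Ships a synthetic-data generator (toy taxon reconstructions, food
    tables, abundance profiles with analytic ground truth) so the whole
    pipeline is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    boot,
    pracma,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'community.R'
    'diet.R'
    'medium-completion.R'
    'recon-io.R'
    'screening.R'
    'solver-core.R'
    'solver-ipm.R'
    'synthetic-data.R'
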