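Package: sarrachem
Title: Metabolite Profiling and Chemotaxonomic Concordance for Pitcher Plants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for GC-MS metabolite profiling of the
    carnivorous pitcher plants Darlingtonia and Sarracenia: assembly of
    quantitative (relative peak area) and qualitative (presence/absence)
    compound tables from peak identifications, sparse hierarchical
    clustering with a lasso-type feature-selection penalty, a
    phylogeny-chemistry concordance test based on within- and between-clade
    distances averaged over enumerated bijective sample-to-tree maps,
    unique-compound cataloguing with floral-scent flagging, and rule-based
    selected-ion-monitoring (SIM) detection of the alkaloid coniine.
    Includes a synthetic-data generator with recoverable ground truth so
    every stage is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
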