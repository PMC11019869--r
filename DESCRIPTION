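Package: riveremf
Title: Ecosystem Multifunctionality and Microbial Co-Occurrence Networks
    Along Latitudinal Gradients
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to score ecosystem multifunctionality (EMF) from tables of
    ecosystem-function measurements (averaging, category-weighted and
    multiple-threshold indices after directional adjustment and min-max
    standardization), to analyse microbial community composition (alpha
    diversity, Bray-Curtis/NMDS/ANOSIM), to infer co-occurrence networks from
    FDR-filtered Spearman correlations with per-sample subnetwork topology and
    a principal-component network-complexity index, and to relate all of these
    to a latitudinal gradient via regressions, threshold-slope curves,
    rank-based group contrasts and correlation screens. Includes a synthetic
    generator for river-site function tables and genus abundance matrices with
    planted latitude effects and correlated taxon guilds, so every stage can be
    validated against a known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vegan,
    igraph,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
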