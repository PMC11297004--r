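Package: pelkit
Title: Potential Energy Landscape Exploration for Coarse-Grained RNA Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for exploring potential energy landscapes of small molecular
    models: basin-hopping global optimisation, doubly nudged elastic band and
    hybrid eigenvector-following transition-state searches, kinetic transition
    networks with persistent plain-text databases, superbasin/disconnectivity
    analysis with funnel identification and minimax barrier queries,
    per-nucleotide structural descriptors of RNA ensembles (sugar pucker,
    backbone dihedrals, base pairing and stacking, dot-bracket strings with
    pseudoknot support), and cross-model energy re-ranking diagnostics.
    Ships analytic benchmark surfaces, Lennard-Jones clusters and a
    coarse-grained RNA chain model with swappable parameter sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    xml2,
    knitr
Config/testthat/edition: 3
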