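Package: rignet
Title: Rigidity Analysis of Protein Constraint Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds body-bar constraint networks from protein structures
    (covalent bonds, hydrogen bonds, salt bridges, hydrophobic tethers),
    computes rigid cluster decompositions with the (6,6) pebble game,
    simulates thermal unfolding by constraint dilution to estimate the
    rigidity phase-transition temperature, derives rigid-contact stability
    maps aggregated over dimer interfaces and secondary-structure elements,
    correlates ensemble phase-transition temperatures with host growth
    temperature, and screens dimer interfaces for interchain disulfide
    designs. Includes synthetic-structure generators (ideal helices, toy
    dimers with planted interactions, coordinate-perturbed ensembles,
    random body-bar multigraphs) so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
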