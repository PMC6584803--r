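Package: connexitope
Title: Epitope Mapping and Selectivity Analysis for Antibody-Bound
    Connexin Hemichannels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for antibody-hemichannel complexes: residue-pair
    interaction probabilities from molecular-dynamics frame series, epitope
    footprint extraction and binding stoichiometry for hexameric connexin
    channels, docking-pose orientation filtering, epitope-motif conservation
    scanning across the human connexin family with selectivity prediction, and
    validation against residual hemichannel conductance measurements. Includes
    seed-deterministic synthetic generators (toy complexes, contact-scheduled
    trajectories, labelled pose sets, patch-clamp current traces) and bundled
    literature-derived reference tables for the abEC1.1-hCx26 system.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
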