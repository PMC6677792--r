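Package: msmatch
Title: In Silico MS/MS Spectral Libraries: Storage, Search and Cosine Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building and searching libraries of multi-collision-energy
    in silico MS/MS spectra for large chemical inventories. Provides an elemental
    formula engine (Hill notation, monoisotopic masses, adduct m/z), readers and
    writers for a multi-energy predicted-spectrum flat format and its companion
    chemical-metadata table, an embedded relational spectral store with indexed
    parent-mass (ppm window) and formula retrieval, fragment matching within a
    mass-accuracy window with per-energy cosine dot-product scoring and
    metadata-augmented candidate ranking, and a seeded synthetic-library
    generator for end-to-end recovery experiments. A command-line interface
    wires the pieces into build / search / convert / simulate workflows.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
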