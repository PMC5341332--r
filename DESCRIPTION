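Package: surfacemap
Title: Differential Cell-Surface Proteomics by Spectral Counting and Targeted PRM
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-arm cell-surface proteomics analysis pipeline: N-glycopeptide
    sequon (NxS/T) validation after PNGase F deamidation, target-decoy peptide
    FDR filtering with q-value estimation, parsimony protein grouping,
    spectral-counting differential abundance by exact binomial test with
    Benjamini-Hochberg FDR, subtractive surfaceome classification
    (condition-unique vs upregulated), annotation enrichment arithmetic against
    surface-protein reference lists (CSPA, CD molecules, pathway membership),
    non-redundant two-platform surface-map merging, and parallel reaction
    monitoring (PRM) quantitation against heavy-isotope-labeled internal
    standard peptides. Includes a seeded synthetic-data generator that emulates
    a two-condition surface-capture experiment with planted ground truth, so
    every stage is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
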