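Package: sepmotif
Title: Conservation Profiling and Constrained Motif Scanning for Protein
    Family Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to analyse conservation of the separase N-terminal
    regulatory domain and similar alpha-solenoid protein families.
    Classifies multiple-alignment columns per taxonomic group (identical,
    class-conserved, unconserved), finds universally conserved positions,
    scans sequences for literal/wildcard motifs with positional context
    constraints (such as the CxCxxC cysteine motif with a histidine 4-6
    residues upstream), surveys clades for motif presence, maps conserved
    positions onto structure coordinates with a beta-carbon contact
    criterion, checks conserved positions against variant tables, and
    generates fully seeded synthetic alignments, sequences and structures
    with machine-readable ground truth so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
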