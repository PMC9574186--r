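Package: zfkit
Title: Characterization of Plant C2H2 Zinc-Finger Protein Families
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for genome-wide characterization of the plant C2H2
    zinc-finger protein (C2H2-ZFP) family. Detects C2H2 zinc-finger
    domains in protein sequences with a variable-spacer pattern scanner,
    classifies each domain into Q/M/Z/D types from the QALGGH motif and
    ligand spacing, computes protein physicochemical properties (MW, pI,
    GRAVY), derives gene structure, chromosomal distribution, tandem and
    segmental duplicates and 2-kb promoters from GFF3 gene models, counts
    stress-related cis-acting elements (ABRE, DRE, MBS, G-box), estimates
    Ka/Ks for duplicate pairs by the Nei-Gojobori (1986) method, builds
    neighbor-joining trees, calls dehydration/rehydration differentially
    expressed genes by a three-method intersection rule, clusters stage
    profiles into six fuzzy expression patterns, and aggregates everything
    into family-level reports. A synthetic-data module generates all
    inputs with known ground truth so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
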