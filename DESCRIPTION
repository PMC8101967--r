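Package: tircurator
Title: Curation of Merlin-Like TIR DNA Transposons in Genome Assemblies
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery and structural curation of Merlin-superfamily DNA
    transposons in genome assemblies: translated homology search for
    transposase copies, detection of the three conserved residue blocks
    carrying the D-D-E catalytic motif, inference of element boundaries from
    multi-copy alignments, detection of imperfect terminal inverted repeats
    (TIRs) and 8-9 bp target site duplications (TSDs), classification of
    copies into families, groups and remnants, annotation of internal tandem
    repeats, screening for bacterial contamination, and preparation of
    filtered and trimmed domain matrices for phylogenetic inference. Includes
    a synthetic-genome simulator that plants elements with full ground truth
    so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    ape,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    phangorn
SystemRequirements: BLAST+ (makeblastdb, tblastn), MAFFT
Config/testthat/edition: 3
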