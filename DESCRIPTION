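Package: phannot
Title: Phage Genome Annotation Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bespoke computational stages of a phage genome annotation
    pipeline as a standalone library and command-line tool: naive six-frame
    ORF calling with phage start-codon filtering, Shine-Dalgarno
    ribosome-binding-site detection and gene-model annotation, candidate
    spanin (phage lysis gene pair) discovery from transmembrane and lipobox
    evidence, interrupted-gene detection from protein-alignment evidence,
    rho-independent terminator promotion criteria, Dice-coefficient
    comparative-genomics tables, and seeded synthetic fixtures with known
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    BiocGenerics
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
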