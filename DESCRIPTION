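Package: plescout
Title: Structural Annotation of Penelope-Like Retroelement Loci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for structural annotation of Penelope-like retroelements
    (PLEs) in genomic loci: detection and resolution of pseudo-LTR terminal
    repeats (direct/inverted arrangements, overlaps, truncations and the
    optional 3' tail), target-site-duplication and microhomology inference at
    insertion junctions, palindrome and core-promoter motif scanning, ORF
    discovery with defect classification and asparagine-rich insert detection,
    pLTR-framed gene-capture detection with allelic empty-site verification,
    identity-based family classification with neighbor-joining summaries, and
    small-RNA sense/antisense polarity profiling.  A seeded locus generator
    produces synthetic PLE insertion loci, allelic pairs and small-RNA
    libraries with machine-readable ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
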