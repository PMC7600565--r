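Package: mitoedit
Title: Detection and Annotation of C-to-U RNA Editing in Plant Mitochondrial ORFs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects C-to-U RNA editing sites in plant mitochondria-encoded
    open reading frames from two evidence channels, per-position nucleotide
    counts derived from aligned RNA-seq reads and C/T peak-height ratios from
    Sanger chromatograms, reconciles the two methods into a final site set,
    annotates codon-level consequences (synonymous and nonsynonymous changes,
    start and stop codon creation, hydropathy transitions), and computes the
    descriptive statistics of an editing-site catalogue. Includes a synthetic
    data generator that plants editing sites with known levels and simulates
    both measurement channels, so the whole pipeline can be validated against
    ground truth without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
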