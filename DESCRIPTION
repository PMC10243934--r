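Package: srnacount
Title: Hierarchical Classification and Quantification of Small RNA-Seq Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-driven counting of small RNA sequencing alignments with
    single-nucleotide control over positional overlap, 5' nucleotide, read
    length, strand, and mismatches. Reads are assigned to annotated features
    through a three-stage selection scheme: feature retrieval by GFF
    attributes, positional-overlap and mismatch selection against a
    piecewise-constant genomic interval index, and read-attribute matching
    with hierarchy-based tie resolution. Multi-mapping sequences are shared
    across alignments and features by the (n/m)/k scheme, with optional
    reads-per-million or custom library normalization. Collapsed-read SAM
    input (counts embedded in read identifiers) is supported, as is a
    GFF-less mode in which every reference sequence is one feature. Includes
    a deterministic synthetic-data generator with a brute-force assignment
    oracle for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Rsamtools,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    yaml,
    utils,
    stats,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
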