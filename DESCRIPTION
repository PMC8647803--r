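Package: sineupscreen
Title: Structural Screening and Domain Annotation of Natural SINEUP Antisense lncRNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies candidate natural SINEUP long non-coding RNAs among
    differentially expressed genes by a four-stage structural screen (lncRNA
    biotype, embedded inverted SINE transposable element, antisense exonic
    overlap with a protein-coding gene, overlap of the sense translation
    initiation site), annotates the SINEUP binding and effector domains on
    candidate sense/antisense pairs, designs domain-deletion mutant
    sequences, and provides the expression-side statistics used to
    characterise such pairs (2^-ddCq relative quantification, tissue-panel
    relative expression, sense/antisense-versus-regulator linear
    regressions). A synthetic-locus generator produces GTF, RepeatMasker and
    differential-expression fixtures with planted candidates and
    single-violation decoys so the whole pipeline is testable without any
    external download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    BiocGenerics,
    IRanges,
    Biostrings,
    data.table,
    MASS,
    stats
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
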