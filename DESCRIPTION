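Package: sporevar
Title: Low-Frequency Variant Analysis for Multinucleate Single-Spore Amplicon Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for dissecting within-spore allele
    diversity of the Rhizophagus irregularis alternative oxidase (RiAOX)
    amplicon, and of any comparable single-gene deep amplicon design. Reads
    are placed on the reference with a semi-global aligner using explicit
    mismatch/gap costs and length/similarity acceptance filters; low-frequency
    variants are detected from quality-screened pileups with neighborhood
    quality filtering and homopolymer (pyro-error) indel removal, classified
    as SNV/MNV/Ins/Del/Repl, compared across spores and isolates under
    frequency thresholds, and annotated for amino-acid consequences against an
    exon/intron gene model. A truth-annotated synthetic read generator
    emulates heterokaryotic multinucleate spores so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    knitr
Config/testthat/edition: 3
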