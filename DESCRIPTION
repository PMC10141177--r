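Package: dbdrescue
Title: Error Tracking and DNA-Binding Domain Recovery for Fungal
    Transcription Factor Annotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects fungal GAL4-like transcription factor gene models that
    carry a middle homology domain (MHD) but no DNA-binding domain (DBD),
    diagnoses the underlying genome annotation or assembly error
    (frameshift, scaffold split, wrong start codon), and recovers the
    missing Zn2C6 or C2H2 zinc-finger domain from genomic sequence.
    Provides translated six-frame local search and a spliced
    protein-to-genome aligner with GT-AG introns, reference-panel nearest
    neighbor search, position-specific profile validation with empirical
    null calibration, a synthetic fungal gene cohort generator with planted
    annotation errors and full truth labels, and summary reporting of
    error spectra and domain-architecture distributions before and after
    rescue.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    Rcpp,
    methods,
    stats,
    tools,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
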