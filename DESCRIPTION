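Package: nanobarcoder
Title: Large-Scale DNA Barcoding from Multiplexed Nanopore Amplicon Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for high-throughput COI DNA barcoding with 1D nanopore
    amplicon reads. Covers the full desk side of the workflow: design and
    validation of error-tolerant 13-nt dual-index tags, error-tolerant
    demultiplexing of basecalled reads (primer search, homopolymer-compressed
    tag matching against a precomputed mutant index, splitting of ligated
    double amplicons), majority-rule consensus barcode calling with
    realign-and-vote polishing, reading-frame-based indel correction and
    strict-consensus consolidation of barcode tracks, quality control against
    reference barcodes, molecular operational taxonomic unit (mOTU)
    delimitation by objective clustering, partition congruence via the match
    ratio, Chao1 species-richness estimation, and coverage-based re-pooling
    plans for a second sequencing pass. A read simulator with known ground
    truth supports end-to-end validation of every stage.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
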