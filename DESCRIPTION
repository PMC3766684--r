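Package: prc2peaks
Title: Window-Based ChIP-Seq Peak Calling and Polycomb Target Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for locating Polycomb Repressive Complex 2
    (PRC2) binding sites from ChIP-seq read data: 5' read extension to
    fragments, normalized fixed-width window density tracks, log2
    treatment/input enrichment with threshold-and-merge candidate peak
    formation, exact binomial significance with Benjamini-Hochberg q-values,
    co-location analysis of two chromatin marks, peak-to-gene assignment,
    metagene signal and motif positional profiles, IUPAC consensus motif
    scanning, gene-set comparison and hypergeometric category enrichment.
    Includes a deterministic synthetic-data generator (genome, gene models,
    enrichment domains with known truth, reads, embedded motifs) so every
    stage can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    data.table,
    jsonlite,
    withr,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
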