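Package: cnatac
Title: Single-Cell Copy-Number Alteration Calling from scATAC-seq Read Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls per-cell copy-number alterations (loss/normal/gain) from
    single-cell ATAC-seq fragment counts. Reads are binned into fixed-width
    genomic windows, filtered against blacklisted regions and low-coverage
    cells/bins, and GC-corrected with a LOESS fit; each cell's genome is then
    segmented per chromosome by iterative binary segmentation maximizing the
    two-sample Anderson-Darling distance between left and right count
    distributions, weak breakpoints are pruned against the cell's genome-wide
    mean distance, and every segment is assigned a copy state from its rounded
    trimmed-mean fold change over the genome-wide mean. Includes Ward
    clustering of karyotypes into clones, pseudo-bulk concordance metrics
    (MSE, precision/recall/F1, state retention under downsampling), and a
    clone-structured synthetic fragment generator so the whole pipeline can be
    exercised and benchmarked without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    graphics,
    grDevices,
    Matrix,
    jsonlite,
    GenomicRanges,
    IRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse,
    rtracklayer
Config/testthat/edition: 3
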