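Package: selannot
Title: Quality Control of Selenoprotein Gene Annotations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Utilities for assessing selenoprotein gene annotations.
    Selenoproteins contain selenocysteine (Sec, U), encoded by an in-frame
    UGA codon that standard annotation pipelines typically read as a stop,
    so public gene sets frequently truncate, skip or misframe these genes.
    The package classifies database GTF/GFF coding-sequence annotations
    against Sec-aware gene predictions into a strand- and frame-aware
    annotation-status taxonomy (well annotated, stop codon, upstream,
    downstream, skipped, out of frame, spliced, absent); assigns predicted
    proteins to subfamilies (orthologous groups) by average weighted
    sequence identity (AWSI) against curated anchor alignments; and filters
    predicted selenoproteomes against lineage-specific expected gene
    counts, reporting kept, filtered-out and missing genes. A seeded
    synthetic-fixture generator produces every input format with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
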