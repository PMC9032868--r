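Package: isoscan
Title: Full-Length Transcriptome Post-Processing for Iso-Seq Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained toolkit for post-processing full-length
    transcriptome (Iso-Seq style) reads without a reference genome:
    classification of circular consensus reads into full-length non-chimeric
    (FLNC), non-full-length and chimeric classes by primer and poly(A)
    evidence; greedy identity clustering of FLNC inserts into isoform groups
    and collapse to a non-redundant transcript set; MISA-style microsatellite
    (SSR) mining with compound-SSR grouping; longest-ORF coding-region
    prediction with completeness classes; consensus long non-coding RNA
    screening across coding-potential methods; and detection of candidate
    alternative-splicing events between transcript pairs from paired
    high-scoring segment pairs separated by an internal gap. Includes a
    deterministic synthetic-read generator that plants primers, poly(A)
    tails, SSRs, ORFs, isoform families and splicing pairs together with a
    machine-readable truth table for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
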