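Package: isoAPA
Title: Isoform Collapse and Alternative Polyadenylation Analysis from
    Full-Length Long Reads
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of full-length non-chimeric (FLNC) long-read
    alignments from developing fruit transcriptomes: collapse of read
    alignments into distinct splice isoforms by intron chain, genome-wide
    poly(A)-site calling from read 3' ends with usage filtering and
    major-site selection, intronic polyadenylation detection, Fisher
    exact tests for differential poly(A)-site usage between developmental
    stages, classification of local alternative-splicing events into
    seven types with percent-spliced-in quantification, nucleotide
    composition profiles around cleavage and splice sites, structural
    pre-filters for long non-coding RNA candidates, and a synthetic-data
    generator with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
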