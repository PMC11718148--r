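Package: retroscribe
Title: Repeat Discovery from Genome Skims and Quantification of Repeat
    Transcription
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Clusters genome-skimming reads into repeat families under a
    percent-identity/coverage criterion, builds consensus contigs, computes
    per-cluster genome proportions, modal pairwise sequence similarity and
    GC content, structurally annotates LTR retroelements (LTR pair, primer
    binding site, target site duplication) and classifies them as complete
    or incomplete, quantifies repeat transcript proportions in poly-A and
    ribo-depleted RNA-seq libraries, and fits linear models relating
    transcript proportion to genome proportion, GC and sequence similarity.
    Includes a synthetic genome and transcriptome generator with a
    ground-truth manifest for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
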