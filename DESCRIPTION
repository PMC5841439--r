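Package: spliceDAS
Title: Differential Alternative Splicing, Cross-Species Conservation, and
    Splicing-Factor Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Annotation-based enumeration of alternative-splicing events of
    seven types (exon skipping, alternative 5'/3' splice sites, mutually
    exclusive exons, intron retention, alternative first/last exons),
    junction-anchored isoform read counting, beta-binomial (two-category
    Dirichlet-Multinomial) likelihood-ratio testing of percent-spliced-in
    changes between sample groups, cross-species conservation calling of
    exon-skipping events with pairwise isoform sequence matching,
    splicing-signature connectivity mapping for splicing-factor discovery,
    and term enrichment with an odds-ratio-threshold Fisher null. Includes a
    seeded synthetic two-species data generator with planted ground truth for
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
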