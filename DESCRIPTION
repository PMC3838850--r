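Package: genechain
Title: Evidence-Anchored Exon Chaining for Gene Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A lightweight gene-prediction toolkit for newly sequenced genomes.
    Candidate coding exons are enumerated and scored ab initio from position
    weight matrices for splice/translation signals and a frame-specific Markov
    coding model, then assembled into gene structures by a dynamic-programming
    exon-chaining algorithm in which introns inferred from spliced EST
    alignments act as anchors: the optimal chain maximizes the number of
    EST-confirmed introns first and the summed exon score second. Includes an
    EST alignment filter and splice-site-compatibility clusterer, a consensus
    intron caller with canonical GT-AG refinement, assembly of non-mergeable
    EST transcripts, two alternative-isoform combination procedures, a
    multi-level (nucleotide, exon, intron, gene, transcript) accuracy
    evaluator with best-transcript-pair mode, and a seeded simulator of
    genomes, gene structures and EST alignments for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
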