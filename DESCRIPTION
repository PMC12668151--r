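Package: g4atac
Title: Integrative Analysis of Chromatin Accessibility and G-Quadruplex
    Occupancy Across an Age Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end, testable implementation of an integrative
    epigenomic analysis of ATAC-seq chromatin accessibility and G-quadruplex
    (G4) CUT&Tag occupancy across an ordinal age series of primary cell
    cultures. Provides cutsite processing and background-anchored trimmed-mean
    coverage normalization, hierarchical genomic peak annotation, canonical G4
    motif scanning, multi-step M/A G4 peak refinement, ordinal-age moderated
    regression with empirical-Bayes variance moderation and a consensus
    culture (block) correlation, conservative confidence-bound effect-size
    shrinkage with ATAC-by-G4 quadrant classification, and context-split
    over-representation and preranked gene-set enrichment combined with
    Fisher's method. A synthetic-data module generates genomes with planted
    canonical G4 motifs, transcript models, peaks, and negative-binomial
    coverage matrices with known ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    fgsea,
    limma,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
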