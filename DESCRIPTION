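Package: tefoot
Title: Consensus-Anchored ATAC-Seq Footprinting for Transposable-Element Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Discovers candidate transcription-factor regulators of
    transposable-element (TE) families from bulk ATAC-seq data in early
    embryos. Tn5 insertion sites are aggregated over length-intact genomic
    copies of each TE family in the coordinate frame of the family consensus
    sequence, producing per-stage insertion-frequency meta-profiles. Local
    depletions of insertion signal relative to flanking signal (footprints)
    are called with an explicit depletion statistic, the underlying consensus
    sequence is matched against a position-weight-matrix library with an
    ungapped Euclidean-distance alignment and permutation E-values, and
    candidates are filtered by single-cell embryonic expression. Downstream
    utilities aggregate a binding signal track (e.g. CUT&Tag) over TE
    insertions and transcription start sites and compare expression
    fold-changes of genes neighbouring bound insertions. A fully specified
    synthetic-data generator plants TE copies, occupancy-dependent Tn5
    protection, motifs and expression ground truth so the whole pipeline is
    testable without any external download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
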