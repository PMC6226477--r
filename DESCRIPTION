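Package: g4rpseq
Title: Transcriptome-Wide RNA G-Quadruplex Landscape Profiling from
    Pulldown Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for G4RP-seq style experiments, in which
    transiently folded RNA G-quadruplexes (G4-RNAs) are captured from
    crosslinked cells with a biotinylated G4 probe and identified by
    sequencing against a matched input library. Provides quadparser-style
    predicted-G4 (pG4) motif scanning at configurable stringencies
    (G3L1-7, G3L1-5, G2L1-10), median-of-ratios count normalization,
    per-gene Enrichment Scores (pulldown/input) and ligand-induced
    Enrichment Score Changes with the associated abundance and
    fold-change filters, landscape statistics (feature regressions,
    top-versus-bottom ranked comparisons, target-list overlap), in vitro
    assay computations (FRET melt T1/2, capture efficiency, qPCR fold
    change, dose-response LDx), and a fully specified synthetic-data
    generator with latent folding ground truth for validating the
    pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    DESeq2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
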