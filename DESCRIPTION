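Package: cistrans
Title: Cis/Trans Decomposition of Strain-Specific Gene Regulation from
    F1 Hybrid and Chimera Designs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decomposes effects of natural genetic variation on gene
    expression and chromatin into cis, trans, mixed, environmental
    (non-cell-autonomous) and cell-autonomous components using F0
    parental, F1 hybrid allelic, and bone-marrow chimera designs.
    Provides variant-aware pseudogenome construction with invertible
    coordinate maps and perfect-match allelic read assignment, an
    internal negative-binomial differential/allelic-bias test,
    position-weight-matrix motif-mutation association by paired
    signed-rank statistics, variant-frequency-by-fold-change summaries,
    basal-state partitioning of stimulus responses, and ligand-activity
    scoring against a ligand-target prior. A synthetic-data module
    generates diploid genomes, reads, design-arm count matrices, motif
    landscapes and ligand networks with planted ground truth so the full
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    MASS,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
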