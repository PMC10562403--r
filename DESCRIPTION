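Package: perturbtag
Title: Tag Counting, Demultiplexing and Combination Scoring for
    Multimodal CRISPR Perturbation Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Processes antibody-derived tag (ADT), hashtag oligo (HTO) and
    guide-derived oligo (GDO) read data from high multiplicity-of-infection
    CRISPR perturbation experiments with CITE-seq readouts. Builds per-modality
    UMI count matrices with conflict filtering of ambiguous cell-barcode/UMI
    pairs, applies per-cell quality filters, demultiplexes hashtags to separate
    droplet doublets from multi-guide cells, calls per-cell guide combinations,
    normalizes surface-protein tags, and scores and ranks perturbation
    combinations by a combined co-stimulation protein score. Also provides
    rank-based gene-signature scoring, Wilcoxon rank-sum differential
    expression, pooled-screen guide enrichment statistics, contingency-table
    residual analysis, and a fully seeded synthetic-data generator with ground
    truth for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    data.table,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    Biostrings
Config/testthat/edition: 3
RoxygenNote: 7.3.3
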