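Package: chromalink
Title: Linking Chromatin Accessibility to RNA and Protein Abundance in
    Multi-Omic Cancer Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An integrative epigeno-proteomics toolkit for patient-matched
    cohorts profiled by ATAC-seq, RNA-seq and isobaric-label (TMT-style)
    proteomics across disease states. Implements summit-based peak-set
    construction, the per-layer normalization chains (log-CPM plus quantile
    normalization for peak counts, gene-body accessibility RPKM, and
    reference-channel peptide-to-protein rollup), Welch two-group
    differential testing with Benjamini-Hochberg control, correlation-based
    peak-to-gene linkage against a per-gene trans-peak Gaussian null,
    sample-wise and gene-wise cross-omic correlation summaries, the
    interaction-model protein predictive significance test (split-sample and
    modified variants), differential transcription-factor footprint set
    logic, and permutation enrichment of protein-protein interaction
    networks. A fully synthetic multi-omics cohort generator with planted
    accessibility-RNA-protein couplings makes every stage testable without
    access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    limma,
    pracma,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
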