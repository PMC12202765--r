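Package: scValley
Title: Single-Cell Nucleosome-Free-Region Landscapes Around Transcription
    Factor Binding Sites
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Maps nucleosome-free-region (NFR) landscapes from single-cell
    MNase-seq fragment data. Fragment midpoints (nucleosome dyad proxies) are
    piled up around candidate transcription-factor binding-site centers and
    summarised by a summit-distance statistic that quantifies per-cell
    accessibility of the inter-nucleosomal valley. The resulting cell-by-motif
    matrix drives quality filtering, winsorisation, variability-based feature
    selection and tree- or graph-based cell clustering. Active motifs are
    called per cell (or per pooled group) with a nucleosome-free score joined
    to a contingency-table independence test, and cluster-specific motifs by
    hypergeometric enrichment. Includes JASPAR PFM parsing and log-odds genome
    scanning with an exact score-distribution threshold, a ground-truthed
    synthetic scMNase-seq simulator, and a clustering evaluation harness
    (Hungarian label matching, overall accuracy, Cohen's kappa, repeated
    stratified-subsampling robustness protocol). An scATAC-seq fragment-length
    mode is provided for cross-modality use.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    data.table,
    jsonlite,
    S4Vectors,
    IRanges,
    Biostrings,
    SummarizedExperiment,
    igraph
Suggests:
    testthat (>= 3.0.0),
    uwot
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Epigenetics, NucleosomePositioning, SingleCell, Clustering,
    MotifAnnotation
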