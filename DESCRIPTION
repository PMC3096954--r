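Package: claudinlow
Title: Claudin-Low Breast Cancer Subtyping, Differentiation Scoring and
    Cohort Simulation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for characterizing the claudin-low intrinsic subtype of
    breast cancer from gene-by-sample log2 expression matrices: probe
    filtering and gene-level collapsing, median-centering and sample
    standardization, two-class SAM (significance analysis of microarrays)
    gene selection with permutation-estimated false discovery rates,
    Euclidean and Spearman nearest-centroid subtype predictors with a
    claudin-low override rule, a distance-weighted-discrimination (DWD)
    mammary differentiation score along the MaSC-pL-mL axis, gene-signature
    mean scoring with average-linkage dendrogram cluster extraction, and
    the association and survival statistics (chi-square, Fisher,
    Kaplan-Meier, log-rank, Cox) used to characterize subtypes clinically.
    Includes a synthetic cohort generator emulating the subtype-specific
    gene-module structure, cell-line panels and sorted mammary epithelial
    populations so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    survival,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
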