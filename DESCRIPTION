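Package: omniblock
Title: Multiblock Hierarchical PLS-DA for Untargeted Metabolomics and
    Lipidomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end discrimination analysis of untargeted LC-MS
    feature tables from matched two-group cohorts. Implements QC-anchored
    LOESS signal-drift correction, blank filtering, coefficient-of-variation
    filtering and probabilistic quotient normalization; NIPALS PCA, PLS-DA
    and OPLS-DA with variable importance in projection (VIP), cross-validated
    Q2, permutation testing and CV-ANOVA; compression of functional
    metabolite blocks and Ward lipid clusters into composite scores for a
    hierarchical (multiblock) PLS-DA; VIP plus t-test feature selection with
    signed fold changes and Benjamini-Yekutieli FDR control; shrinkage
    partial-correlation network analysis with betweenness centrality; and
    hypergeometric pathway over-representation analysis. Ships a synthetic
    cohort generator with known ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
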