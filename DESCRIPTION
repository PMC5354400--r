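Package: ductnet
Title: Regulator-Network Hierarchies and Mammary Ductal Tree Morphometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two analysis chains for studying receptor-driven disruption of
    mammary epithelium. The transcriptomics chain screens a two-group
    expression matrix for differentially expressed genes (folded variation
    factor with Benjamini-Hochberg control), tests gene-set
    over-representation by the hypergeometric law, layers relation-typed
    regulator digraphs into hierarchical networks by iterative
    minimal-level identification, and extracts intermediate regulators
    common to several cellular functions. The imaging chain quantifies
    whole-mount ductal trees: multiscale Hessian (Frangi) vesselness
    enhancement, hard-threshold segmentation, topology-preserving
    skeletonization, and extension/branching/sprout morphometry with
    unpaired group comparison. A synthetic-data module generates
    expression matrices, gene-set collections, layered regulator graphs
    and rendered branching-tree images with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    png,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
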