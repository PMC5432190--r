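Package: cloneclust
Title: Clustering Cancer Subclonal Evolutionary Trees by Reference-Tree
    Registration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares and clusters rooted cancer evolutionary trees whose
    edge lengths count somatic single nucleotide variants (SSNVs).  Trees of
    different sizes and topologies are registered onto a common complete
    bifurcated reference tree, their edge lengths are normalized within each
    tumor, and the resulting fixed-length vectors are clustered with Ward's
    method, with the number of clusters chosen by the gap statistic.
    Includes classical multidimensional scaling and sub-clonal diversity
    (lineage-through-time style) curves for cluster interpretation, a
    labeled-cohort simulator for benchmarking, and external clustering
    validation indices (purity, normalized mutual information, Rand index).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    cluster,
    dplyr,
    generics,
    ggplot2,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
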