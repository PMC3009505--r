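Package: glyqgram
Title: Weighted q-Gram Kernels for Glycan Structure Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Kernel methods for classifying glycans from their rooted,
    labeled tree structures. Glycans are read from KCF-style text records,
    decomposed into q-grams (connected q-node subtrees of maximum internal
    degree two), and compared through plain q-gram count kernels or weighted
    kernels that admit similarity between distinct q-grams. Inter-q-gram
    similarity can be scored from glycosidic-linkage, monosaccharide and
    layer similarity (Linkage kernel), from dynamic-programming tree
    alignment of the q-gram structures (KCaM kernel), or both (Linkage KCaM
    kernel). Similarity matrices are corrected to positive semidefiniteness
    by eigenvalue clipping, kernels over several q can be combined with
    fixed or alignment-derived weights, and glycans are classified with
    support vector machines on the precomputed kernels under repeated
    stratified cross-validation scored by AUC. A seeded generator of random
    labeled glycan trees and planted-motif two-class datasets supports
    benchmarking without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    kernlab,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
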