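Package: cnvcomplexity
Title: Subclonal Complexity Scores from Single-Cell Copy-Number Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies intra-tumor subclonal complexity from single-cell
    copy-number variation (CNV) matrices, such as the discrete HMM state
    output of InferCNV. Provides a Shannon-entropy complexity score over
    binned per-gene gain/loss frequencies, a per-cell CNV fluctuation score
    with kernel-density threshold selection for malignant-cell calling, a
    clonal-structure simulator producing labelled monoclonal and polyclonal
    single-cell CNV cohorts, two published baseline heterogeneity metrics
    (PCA centroid dispersion and median pairwise correlation distance), and
    ROC/AUC benchmarking utilities, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
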