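Package: kmgselect
Title: Kernel-Matrix Gene Selection for Two-Class Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies differentially expressed genes in two-class
    gene-expression data by scoring the columns of a kernel (Gram) matrix
    with a t-like separability statistic. Implements per-gene ranking
    (KMGS) and greedy sequential forward selection with an incremental
    Gram-matrix accumulator (KMSFS) for linear and Gaussian RBF kernels,
    together with the surrounding experimental protocol: Dudoit-style
    preprocessing and row/column standardization, Fisher's-ratio
    prescreening, external balanced-bootstrap B.632+ error estimation with
    a linear support vector machine, parameter tuning by grid search with
    Friedman rank-sum tests and Holm post-hoc selection, selection-frequency
    reporting with heatmaps, and a synthetic-data generator with planted
    mean-shift and variance-shift genes for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    grDevices,
    jsonlite,
    pheatmap,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
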