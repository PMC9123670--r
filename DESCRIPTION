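Package: regiospec
Title: Region-Specific Gene and Co-Expression Module Detection for
    Multi-Region Expression Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for comparative multi-region transcriptomics:
    FPKM computation and replicate-consistency expression filtering,
    detection of region-specific genes by a three-criterion fold/ratio/quantile
    filter, a weighted gene co-expression network built from first principles
    (soft-power adjacency, topological overlap, hierarchical module detection,
    module eigengenes), module-region association through a one-hot design
    matrix with Pearson correlation and Student-t p-values, candidate-gene
    synthesis, the 2^-ddCt transform for qPCR validation, and a synthetic
    multi-region data generator with planted ground truth for end-to-end
    benchmarking.
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
    jsonlite,
    mclust,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
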