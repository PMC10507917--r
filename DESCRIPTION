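Package: detrem
Title: Capture-Bias-Corrected Cell-Type Deconvolution of Bulk RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates cell-type proportions in bulk RNA-seq samples by
    iterated weighted non-negative least squares against a multi-subject
    single-nuclei RNA-seq signature, with a per-gene capture-quotient
    penalty (the DeTREM weighting scheme extending MuSiC) that
    down-weights genes captured differently by single-nuclei and bulk
    sequencing. Includes a pseudo-bulk simulator with known cell-type
    fractions and gamma- or quotient-derived per-gene capture bias, a
    fully synthetic multi-subject single-nuclei reference generator, an
    evaluation suite (Lin's concordance correlation coefficient, Pearson
    correlation, root mean square error, zero-call quantification,
    min-max-scaled concordance with external measurements), and a
    command-line interface covering the whole pipeline.
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
    Matrix,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
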