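Package: nrcomp
Title: Compression-Based Alignment-Free Comparison of DNA Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Alignment-free comparison of DNA sequences through ideal
    compression code lengths. A soft-blended mixture of finite-context
    (Markov) models and substitution-tolerant context models, with
    inverted-repeat counting and cache-hash bounded memories, estimates
    per-symbol information content in three modes: reference-free C(x),
    conjoint C(xy) and relative C(x||y) with frozen reference memory.
    On top of the estimator the package computes the Normalized
    Compression (NC), the Normalized Compression Distance (NCD, conjoint
    and conditional forms) and the Normalized Relative Compression (NRC),
    per-symbol information profiles with low-information segmentation and
    two-way similarity maps, and ships synthetic-sequence generators
    (uniform, block architectures with mutated copies, repeat-rich) for
    controlled experiments.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    tibble,
    dplyr,
    purrr,
    ggplot2,
    generics,
    withr,
    rlang,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
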