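Package: perturbsem
Title: In Silico Perturbation of Gene Signatures with T-Scores and
    Three-Node Path Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers per-sample molecular activity of a transcriptional
    regulator from a directional target-gene signature via a two-sample
    t-statistic (the T-score), tests joint regulation of a downstream
    reporter by two upstream regulators with a three-node structural
    equation (path) model fitted by maximum likelihood (with RMSEA, CFI,
    TLI and SRMR fit indices), and assesses in silico perturbations of a
    signature with a two-class elimination bootstrap yielding empirical
    p-values. Includes synthetic-data generators with known ground truth
    for all analysis steps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    purrr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
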