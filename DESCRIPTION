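Package: colonyscreen
Title: Colony-Array Growth Screen Analysis with Spatial Normalization and
    FDR Hit Calling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for high-density colony-array growth screens
    of the kind produced by solid-medium phenomics platforms: simulation of
    1536-position plate screens with spatial bias, batch effects and injected
    strain effects; extraction of generation time, lag and yield from growth
    curves; spatial normalization against an interleaved control-strain grid
    (log strain coefficients), plate-median batch correction and log
    phenotypic indices; and hit calling via a Welch test against an
    IQR-restricted null, Benjamini-Hochberg FDR control, control-envelope
    effect-size gating and a non-grower rescue rule. Includes relative qPCR
    expression statistics (geometric-mean reference normalization, 2^dCT),
    gene-level aggregation, replicate-concordance summaries, tidy accessors
    and plotting helpers.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    readxl,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
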