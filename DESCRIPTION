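Package: seminomiR
Title: Peripheral-Blood Small RNA Screening of Seminoma Metastasis Status
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable small RNA sequencing analysis pipeline for
    discriminating metastasized from non-metastasized seminoma using
    peripheral-blood small RNA profiles. Covers adapter trimming and tag
    collapsing of raw reads, annotation against a mature miRNA / non-coding
    RNA reference, per-library read accounting, candidate filtering by read
    depth and fold change, separation-robust (Firth bias-reduced) univariate
    logistic screening, candidate-list overlap statistics, and an exhaustive
    search for pairs of small RNAs whose two-dimensional expression completely
    separates metastasized from non-metastasized samples (exact geometric
    test cross-checked by a linear support vector machine). A synthetic-data
    generator emulating the three-group, five-samples-per-group blood
    small-RNA study design makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    e1071,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
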