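Package: genesetforge
Title: Building and Testing Consensus Gene-Set Collections from
    Expression Microarray Comparisons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for turning probe-level expression
    microarray experiments into curated, direction-split gene-set
    collections. Covers array quality assessment (average background,
    scale factor, percent present, 3'/5' degradation ratios, RLE and
    NUSE), RMA-style preprocessing (background adjustment, quantile
    normalization, median-polish probe summarization with many-to-one
    probe-to-gene mapping), empirical-Bayes moderated differential
    expression with FDR control, surrogate-variable batch correction
    capped at two components, extraction of capped up/down gene sets in
    GMT format, construction of consensus sets across studies of the
    same comparison at 30/50/70 percent support, and enrichment testing
    of query gene lists by over-representation and weighted running-sum
    statistics. Includes a synthetic-data generator with known ground
    truth (differential genes, batch factors, and array failure modes)
    so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    limma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea,
    yaml,
    optparse
Config/testthat/edition: 3
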