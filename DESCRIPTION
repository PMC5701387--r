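Package: sizexpr
Title: Size-Expression Decomposition of Genome-Wide Knockout Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for dual-reporter flow-cytometry knockout
    screens. Computes per-strain population summaries from per-cell events,
    decomposes phenotypes into a cell-size score (S), a size-normalized
    global expression score (E) and a gene-specific imbalance score (G)
    by sequential regression of fluorescence on forward scatter, calls
    extreme phenotypes with quantile and Z-score rules, and tests
    phenotype-function associations with bootstrap co-occurrence nulls and
    Fisher/EASE over-representation statistics with Bonferroni correction.
    Includes a synthetic-screen generator with seeded effect systems for
    end-to-end validation, plus readers and writers for delimited and
    FCS 3.1 event files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
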