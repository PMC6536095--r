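Package: pharmequity
Title: Needs-Based Equity Analysis of Pharmaceutical Assistance Transfers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures how equitably pharmaceutical-assistance resources are
    allocated across regions relative to epidemiological need, using
    output-oriented, variable-returns-to-scale data envelopment analysis (DEA)
    and its subset-ensemble extension (multiple DEA, MDEA). Provides an equity
    index per decision-making unit with standard errors and confidence
    intervals, frontier projections of optimal transfer values, two
    budget-constrained reallocation schemes (complementary and substitution),
    a regression of coverage deficit on pharmacy accreditation, a synthetic
    state-level data generator with a planted efficiency frontier, and bundled
    reference tables of 2013 Brazilian federative-unit transfers for the
    Popular Pharmacy Program (BPPP) and the Basic Component of Pharmaceutical
    Assistance (BCPA).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
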