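Package: meshtrends
Title: Differential Frequency and Trend Analysis of MeSH Annotations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Compares Medical Subject Headings (MeSH) descriptor usage
    between a target and a control sample of MEDLINE articles binned by
    year. Builds per-term frequency panels, tests per-year differences
    with two-proportion chi-square tests, controls the false discovery
    rate with the Benjamini-Hochberg procedure, aggregates evidence
    across years with Fisher's method, scores effect sizes as log2
    frequency ratios with a sentinel for terms absent from the control
    sample, and detects monotone usage trends with the Mann-Kendall test.
    Ships a synthetic annotated-corpus generator with known ground truth
    so the whole pipeline can be validated without network access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
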