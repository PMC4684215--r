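Package: varhom
Title: Tests for Homogeneity of Variances in DNA Methylation Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Seven tests for equality of variances between two groups of
    subjects measured over many CpG sites (F, Bartlett, Levene, trimmed-mean
    Levene, Brown-Forsythe, and the two moderated-t tests on absolute and
    squared deviations), together with the simulation machinery to compare
    them: fixed-distribution two-group scenarios, a hierarchical
    scaled-inverse-chi-squared variance model on the M-value scale, outlier
    contamination, type-I-error and power estimation with a rank summary, and
    a two-cohort discovery/validation workflow with FDR control and an
    IQR-based outlier-site rule.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    limma,
    car,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
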