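Package: ki67seq
Title: Sequential Exact Binomial Classification of Ki67 Proliferation Counts
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scores Ki67 immunohistochemistry by sequential exact binomial
    testing of a 20% positivity cut-off on cumulative 10-cell increment
    counts, with Monte-Carlo calibration of the per-test significance level
    to a target overall type-I error. Includes the paired core-biopsy versus
    surgical-sample comparison battery (paired t-tests on linear and log
    scales, exact Wilcoxon signed-rank, dichotomization with exact McNemar,
    Bland-Altman agreement, repeatability of duplicate reads, and a
    hotspot-dilution contrast), a synthetic counting-sheet generator that
    emulates hotspot-first counting with positivity decay and paired samples
    with a multiplicative offset, and CSV counting-sheet input/output with a
    small command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
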