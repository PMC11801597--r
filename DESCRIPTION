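Package: pvsignal
Title: Disproportionality Signal Detection for Spontaneous Adverse Event Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pharmacovigilance signal detection on spontaneous
    adverse-event reporting data in the FAERS quarterly-extract format.
    Reads dollar-delimited DEMO/DRUG/REAC/OUTC/THER tables (legacy and
    modern layouts), deduplicates case versions, normalizes free-text drug
    names against a curated dictionary, builds per-drug 2x2 contingency
    tables for a target MedDRA Preferred Term, and computes four
    disproportionality statistics (reporting odds ratio, proportional
    reporting ratio with Yates chi-square, the BCPNN information component,
    and the empirical Bayes geometric mean) with their interval bounds and
    standard signal thresholds. Includes a descriptive cohort profiler and
    a synthetic report generator with planted drug-event relative risks for
    validating every pipeline stage against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    dplyr,
    tibble,
    tidyr,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    jsonlite,
    optparse
Config/testthat/edition: 3
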