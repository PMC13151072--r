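Package: pvror
Title: Reporting Odds Ratio Signal Screening for Spontaneous Adverse-Event Report Databases
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Disproportionality analysis of spontaneous adverse-event reports
    in the JADER (Japanese Adverse Drug Event Report database) table layout.
    Reads and links case-level demographic, drug and reaction tables, maps
    MedDRA preferred terms to primary system organ classes, builds 2x2
    report-count contingency tables for an index drug against either all
    other drugs or a named comparator, and computes reporting odds ratios
    with Wald 95% confidence intervals (Haldane-Anscombe continuity
    correction for zero cells), exact two-sided Fisher p-values and
    EudraVigilance-style signal classification. Includes an inverse-recovery
    oracle that reconstructs integer contingency tables from published
    estimates, and a synthetic report-database generator with planted
    reporting-odds effects for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    stringi,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
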