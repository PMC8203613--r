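Package: pvsignal
Title: Disproportionality Signal Detection for Spontaneous Adverse Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A pipeline for pharmacovigilance signal detection on FAERS-style
    spontaneous adverse event report tables. Reads the four relational report
    tables (demographics, drugs, reactions, outcomes), deduplicates cases,
    applies suspect-role, completeness and reporting-period filters, aggregates
    reaction terms through a MedDRA-like dictionary at the preferred-term (PT),
    narrow standardised query (SMQ) and system-organ-class (SOC) levels, and
    screens drug-event pairs with three disproportionality statistics: the
    reporting odds ratio (ROR), the proportional reporting ratio (PRR) with its
    Pearson chi-squared statistic, and the Bayesian confidence propagation
    neural network information component (BCPNN IC). A signal is declared only
    when all three criteria are met. A synthetic report generator with known
    injected drug-event associations supports calibration and parameter-recovery
    studies without access to the real database.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
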