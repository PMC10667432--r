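Package: faersignal
Title: Disproportionality Signal Detection for FAERS-Style Spontaneous Report Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pharmacovigilance pipeline for FDA Adverse Event Reporting
    System (FAERS) quarterly ASCII extracts: reads the DEMO/DRUG/REAC/THER/
    OUTC/INDI tables, removes deleted cases, deduplicates report versions by
    the CASEID/FDA_DT/PRIMARYID rule, builds a primary-suspect drug cohort by
    name matching on DRUGNAME and PROD_AI, and screens drug-event pairs at the
    MedDRA Preferred Term and System Organ Class levels with four
    disproportionality algorithms (reporting odds ratio, proportional
    reporting ratio with Pearson chi-squared, the BCPNN information component,
    and the closed-form empirical Bayes geometric mean) under a four-way
    consensus criterion. Also computes time-to-onset summaries with explicit
    date-exclusion accounting, demographic descriptive tables, and ships a
    seeded synthetic FAERS generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
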