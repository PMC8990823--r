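Package: faersvig
Title: Pharmacovigilance Disproportionality Analysis for FAERS Spontaneous Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
                  role = c("aut", "cre"))
Description: A tested pipeline for spontaneous-report signal detection in the
    FDA Adverse Event Reporting System (FAERS): quarterly-extract ingestion of
    the seven "$"-delimited ASCII tables, FDA-recommended case deduplication,
    case and event identification against Standardised MedDRA Query (SMQ)
    preferred-term lists, cohort construction with primary-suspect exposure
    assignment, reporting odds ratio (ROR) disproportionality with Woolf
    confidence intervals, propensity-score matching with an exact optimal
    caliper matcher, time-to-onset summaries, serious-outcome comparisons, and
    a synthetic FAERS generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
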