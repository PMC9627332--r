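Package: onjsignal
Title: Disproportionality Signal Detection for Antiresorptive-Related
    Osteonecrosis of the Jaw in Spontaneous-Report Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for pharmacovigilance analysis of
    antiresorptive-drug-related osteonecrosis of the jaw (ONJ) in
    FAERS-style spontaneous-report tables: reading and writing the
    quarterly "$"-delimited ASCII dialect, case deduplication and drug
    normalisation, indication mapping to MedDRA-style high-level terms and
    merged indication groups, reporting odds ratio (ROR) signal detection
    with Woolf confidence intervals overall and within indication- and
    dose-frequency strata, time-to-onset summaries with Mann-Whitney
    comparisons, descriptive breakdowns, and a synthetic spontaneous-report
    generator with configurable drug-event odds multipliers so every stage
    is testable without a database download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
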