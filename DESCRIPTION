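Package: faersignal
Title: Disproportionality Signal Detection for FAERS-Style Spontaneous Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pharmacovigilance pipeline for spontaneous
    adverse-event report databases in the FAERS quarterly ASCII dialect:
    ingestion and case-version deduplication, drug-name normalization,
    MedDRA-like term dictionaries, SMQ-based retrieval of
    pregnancy-related reports, event-level 2x2 contingency tables, and
    four disproportionality estimators (ROR, PRR with Pearson chi-square,
    BCPNN information component, and the observed/expected EBGM ratio)
    with a combined six-part signal criterion. Includes a synthetic
    report generator with planted relative risks so the whole pipeline
    is testable without access to the real database.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    rlang,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
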