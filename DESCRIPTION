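Package: nhabx
Title: Antimicrobial Stewardship Indicators for Nursing Homes from Pharmacy Claims
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes a consensus set of 14 quantity metrics and 10 proxy
    indicators of antibiotic use in nursing homes from reimbursement
    (pharmacy-claims) data: dispensing counts and defined daily doses (DDD)
    per 100 resident-days by ATC class, route-of-administration shares,
    urine-culture linkage of antibiotic choices for urinary tract
    infections, seasonal variation, repeat fluoroquinolone courses,
    package-based treatment-duration estimation, same-day NSAID
    co-prescription and flu-vaccine coverage. Each proxy indicator is
    classified against its consensus target band, and facility-level values
    are benchmarked against regional median/IQR summaries. A synthetic
    claims generator with analytically known ground truth emulates the
    structure of national health-insurance dispensing data so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
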