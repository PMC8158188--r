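Package: hipdisloc
Title: Stepwise Code-Combination Detection of Hip Arthroplasty Dislocations
    in Administrative Registry Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating a stepwise code-combination
    algorithm that detects dislocation episodes after primary total hip
    arthroplasty (THA) in hospital-contact registry extracts coded with
    ICD-10 diagnoses and NCSP procedures. Provides cohort construction with
    follow-up windowing and censoring, assignment of contacts to five
    diagnostic code groups, cumulative step classification at patient and
    event level including chart-review adjusted steps, diagnostic accuracy
    metrics (sensitivity, specificity, PPV, NPV) with exact Clopper-Pearson
    confidence intervals, reconstruction of implied confusion-table counts
    from printed accuracy tables, and a calibrated synthetic registry
    generator so the full pipeline can be exercised without access to
    restricted national registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
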