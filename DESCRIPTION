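Package: chemovote
Title: Vote-Weighted Chemotype Association Analysis for Strain Preference Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analyses patient strain-preference surveys against cannabinoid and
    terpene assay panels. Implements vote-weighted constituent averaging over
    production-lot assays, a bounded difference-over-sum association
    coefficient per analyte, summary-level two-sample significance testing,
    survey descriptives (vote tallies, rankings, Likert summaries, side-effect
    tables), and a synthetic-data generator with planted effects for
    calibration and parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
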