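Package: fragilityaudit
Title: Fragility Index Auditing of Randomized Controlled Trial Corpora
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to audit the robustness of evidence from parallel two-arm
    randomized controlled trials with binary outcomes using the Fragility
    Index: an exact-test engine that iteratively converts non-events to
    events until statistical significance is lost, a brute-force verification
    oracle, a trial-corpus data model with eligibility validation and CSV
    input/output, per-treatment-category median/IQR summaries with a
    lost-to-follow-up robustness criterion, and a seeded generator of
    synthetic trial corpora shaped like the set of trials cited by clinical
    practice guidelines for rectal cancer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
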