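Package: laggedsense
Title: Lagged Repeated-Measures Correlation of Smartphone Sensing and Symptom Change
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for digital-phenotyping studies that relate passively sensed
    smartphone behavior to self-reported mental-health symptoms. Computes
    GPS mobility features (location variance, location clusters, entropy,
    circadian movement, distance, velocity), semantic-location, communication
    and app-use daily aggregates; standardizes and combines them into
    unit-weighted feature groups over two-week windows; clusters participants
    on baseline symptom items; and estimates lagged repeated-measures
    correlations between two-week changes in sensed behavior and three-week
    changes in depression, anxiety and social-anxiety severity, in both
    temporal directions, with Benjamini-Hochberg false-discovery-rate
    correction. Includes a seeded synthetic-cohort generator with a tunable
    lagged behavior-to-symptom coupling and missing-not-at-random assessment
    dropout, used for property-based validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    geosphere,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
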