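Package: ehrdq
Title: Study-Specific Data Quality Assessment for Multi-Site EHR Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A catalog-driven engine for study-specific data quality assessment
    of electronic health record data staged in a simplified PCORnet-style common
    data model. Provides readers, writers and conformance validation for the
    six-domain relational model; a multi-site synthetic EHR generator with
    chronic-kidney-disease trajectories, correlated blood pressures and
    injectable data-quality faults tracked in a ground-truth plant registry;
    pediatric estimated glomerular filtration rate (bedside Schwartz) and the
    eleven-step cohort attrition pipeline; aggregate (distributed) and row-level
    check execution rounds; anomaly detection with rule-based issue
    prioritization, theme assignment and cross-round improvement tracking; and
    anonymized cross-site reporting with a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    readr,
    purrr,
    rlang,
    stats,
    utils,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
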