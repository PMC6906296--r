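Package: mswear
Title: Wearable Biosensor Features and Disability Correlations in Multiple
    Sclerosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extracts mobility, balance, activity, sleep and fatigue
    features from body-worn inertial and pulse sensors in people with
    multiple sclerosis, and correlates them with neurologist-assessed
    disability (EDSS, MSFC-4). Covers in-clinic structured sessions
    (timed up and go, two-minute walk, 30-second balance, psychomotor
    vigilance) and multi-day free-living streams (activity
    classification, daily gait aggregates, idle time, wear compliance,
    heart-rate-variability sleep staging). Includes a synthetic-cohort
    generator with planted disability-dependent effects for end-to-end
    validation, Spearman correlation tables with Storey q-value control
    of the false discovery rate, and median-variability-by-days
    analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    signal,
    stats,
    tibble,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
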