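Package: chimpmetrics
Title: Behavioral Welfare Metrics for Sanctuary Chimpanzee Colonies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy toolkit implementing seven behavioral-welfare metric
    protocols for managed chimpanzee colonies: composite wellness scoring
    from multi-assessor surveys with action-band classification, wound
    surveillance with rolling 14-day concern criteria, zone-weighted total
    body hair-loss scoring with escalated monitoring schedules, activity
    budgets from instantaneous scans and continuous focal follows with
    Targeted Individual Assessment triggers, nearest-night-neighbor social
    networks, positive-reinforcement-training and shifting-compliance
    analytics, and an integrated per-animal welfare report. A seeded
    synthetic-colony simulator generates every record stream with known
    ground truth so all metrics are testable without real data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
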