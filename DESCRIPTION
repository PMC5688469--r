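Package: livessaved
Title: Counterfactual Lives-Saved Modelling for Maternal and Newborn Health Portfolios
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A deterministic cohort engine and analysis protocol for
    estimating maternal and newborn lives saved from a donor's health and
    family-planning project portfolio. Implements a compact LiST-style
    model linking changes in health-intervention coverage to cause-specific
    maternal and neonatal mortality through multiplicative residual risks,
    a Bongaarts-index fertility linkage for contraceptive prevalence,
    paired with/without-funder counterfactual projections with donor
    attribution, indicator-to-coverage conversion for heterogeneous
    project registers, geographic grouping and de-duplication, national
    and global aggregation, mortality-source sensitivity analysis, and a
    synthetic-data generator with an independent closed-form truth and a
    per-birth Monte-Carlo microsimulation oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
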