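Package: uprtriage
Title: Multi-Tier Screening Triage and Quantification for ATF6-Selective
    Proteostasis Regulators
Version: 0.1.0
Authors@R:
    person("UPR", "Triage Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for high-throughput screens that seek small
    molecules preferentially activating the ATF6 arm of the unfolded protein
    response. Provides plate normalization to percent-of-control activation
    with Z'-factor quality control, staged hit calling (primary cutoff,
    blacklist filter, 3-SD confirmation, stringency re-application,
    dual-reporter selectivity), reference-normalized geneset activation
    scoring with ANOVA-based UPR profile classification and Ward clustering,
    adaptive-threshold quantification of ATF6 nuclear translocation from
    per-cell intensities, pulse-chase secretion kinetics with
    four-parameter-logistic dose-response fitting, and seeded synthetic-data
    generators with planted ground truth for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
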