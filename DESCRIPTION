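Package: uhcproj
Title: Scenario Projection of Health-Service Scale-Up Costs, Health Impact,
    and Financing Gaps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for projecting the resources needed to scale up health-service
    coverage in low- and middle-income countries over a 15-year horizon
    (2016-2030).  Countries are classified into five health-system typologies
    that gate the speed of scale-up; annual coverage trajectories are built per
    intervention and delivery platform under progress and ambitious scenarios
    against a flatline counterfactual; costs are computed bottom-up (quantities
    times prices) for drugs and supplies, programme support, health workforce,
    infrastructure, supply chain and governance; health impact is projected with
    a cohort-component demographic model, multiplicative mortality-reduction
    effects, abridged life tables, deaths averted and healthy life-years; and
    fiscal space is projected under optimistic and moderate financing scenarios
    to quantify per-country financing gaps.  Includes a seeded synthetic-data
    generator for country profiles and intervention catalogues, and reporting
    helpers that aggregate results into phase, per-person and group summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
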