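Package: hypocost
Title: Decision-Tree Cost-Effectiveness of Drug-Induced Hypoglycemia in
    Older Adults with Type 2 Diabetes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A one-year decision-tree model of drug-induced hypoglycemia for
    six glucose-lowering medication classes in adults aged 65-79 and 80 years
    and older, from the U.S. Medicare and Canadian public payer perspectives.
    Computes per-drug incidence rates of mild and moderate/severe hypoglycemia
    from a multiplicative risk equation (diabetes duration, HbA1c, body mass
    index, glomerular filtration rate), per-person annual costs and
    quality-adjusted life-years, incremental cost-effectiveness ratios with
    dominance classification, one-way (tornado) and probabilistic sensitivity
    analyses with cost-effectiveness acceptability curves, population budget
    impact and disinvestment scenarios, and a patient-level microsimulation
    that serves as a Monte-Carlo oracle for every analytic expectation.
    All model inputs live in editable YAML configuration files with packaged
    defaults for the U.S. and Canada.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
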