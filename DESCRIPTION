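Package: seqcea
Title: Markov Cohort Cost-Utility Modelling for Sequential Rheumatoid
    Arthritis Treatment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A cohort state-transition (Markov) model for cost-utility
    analysis of sequential rheumatoid arthritis treatment: a first-line
    TNF-inhibitor strategy followed by a conventional DMARD sequence and
    palliation. Implements ACR response-based transitions, HAQ-DI tracked
    disability with mapping to EQ-5D utility, HAQ-adjusted background
    mortality, regimen-level drug costing with vial/unit wastage,
    discounting and inflation, incremental cost-effectiveness analysis
    with dominance classification, one-way sensitivity scenarios, and
    probabilistic sensitivity analysis with cost-effectiveness
    acceptability curves. Ships a fully documented synthetic default set
    for inputs that published analyses cite but do not print (life
    tables, follow-up DMARD efficacy, HAQ-band resource costs).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
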