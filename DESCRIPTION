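Package: hmrisk
Title: Dietary Health Risk Assessment for Heavy Metals in Alcoholic Beverages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the US EPA target-hazard-quotient framework for
    assessing the health risk of ingesting heavy metals and ethanol in
    alcoholic beverages: average daily intake (ADI), target hazard
    quotients (THQ), hazard indices (HI) with "1-in-x" risk ratios, and
    incremental lifetime carcinogenic risk from cancer slope factors.
    Includes a descriptive-statistics layer (quartiles, IQR-based outlier
    flagging, composition shares, guideline exceedance), from-scratch Ward
    agglomerative clustering of risk profiles with cophenetic validation
    and split-half stability, non-detect (censored) concentration
    handling, and a seeded synthetic-panel generator emulating sachet and
    artisanal spirit contamination profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    fitdistrplus,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
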