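Package: mcrscreen
Title: Maximum Cumulative Ratio Screening for Chemical Mixtures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tier-0 cumulative risk screening of chemical mixtures measured in
    drinking-water sources. Computes hazard quotients (HQ), hazard indices (HI)
    and the maximum cumulative ratio (MCR = HI / max HQ) for sample-by-analyte
    concentration tables under alternative non-detect treatments (zero or
    detection limit divided by sqrt(2)), applies mean-HQ based data-reduction
    rules, and summarises cohorts with HI-centile subgroup statistics, Kendall
    trend tests and Wilcoxon comparisons. Ships a permitted-dose registry for
    common ground-water contaminants and a calibrated synthetic ground-water
    cohort generator for end-to-end testing without access to survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
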