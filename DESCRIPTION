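Package: soaburden
Title: Health Burden and Social Cost of Aromatic Secondary Organic Aerosol
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates premature mortality and social cost attributable to
    secondary organic aerosol (SOA) formed from aromatic hydrocarbons in
    gasoline. Provides a random-slope mixed model (REML) for bias-correcting
    modeled concentration fields against monitor observations, emissions-based
    source attribution, log-linear concentration-response health impact
    functions with Monte-Carlo uncertainty propagation, and value-of-mortality
    -risk monetization, together with a synthetic-data generator that emulates
    gridded air-quality model output, monitor campaigns, emissions inventories
    and population tables so the full pipeline is testable offline.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
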