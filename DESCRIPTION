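Package: sugarcra
Title: Comparative Risk Assessment of Dietary Free-Sugars Reduction Scenarios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Macrosimulation toolkit for estimating non-communicable disease
    deaths averted or delayed under counterfactual dietary scenarios. Builds
    baseline and counterfactual energy-intake scenarios from a systematic
    fractional reduction in the free-sugars content of foods, translates
    per-stratum calorie changes into shifts of the population BMI distribution
    through a steady-state energy-balance relation, computes cause-specific
    potential impact fractions by numerical integration over lognormal BMI
    distributions, attributes deaths averted per cause, sex and age band, and
    attaches Monte Carlo 95 percent uncertainty intervals driven by
    relative-risk parameter uncertainty. Includes a synthetic-data generator
    that emulates national survey and mortality-registry inputs with known
    ground truth, and a command-line interface for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    pracma,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), withr, knitr, rmarkdown
Config/testthat/edition: 3
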