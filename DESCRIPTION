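Package: ricebench
Title: Yield-Gap and Resource-Use Benchmarking for Rice Cropping Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Per-crop-cycle resource-use accounting for rice cropping
    systems (global warming potential with IPCC Tier-1 style methane
    scaling and a nitrogen-surplus nitrous-oxide model, fossil-energy
    input and net energy yield, partial nitrogen balance and excess
    nitrogen, pesticide environmental-impact-quotient field-use rating,
    labor), yield-gap normalization against simulated yield potential,
    area-weighted aggregation to per-crop and annual system metrics, a
    six-metric overall performance index, correlation reporting, and a
    scenario engine that closes yield gaps to the exploitable ceiling
    under alternative nitrogen-balance assumptions. Includes a seeded
    synthetic-cohort generator emulating the structure of multi-country
    rice farm-survey compilations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
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
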