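Package: phccostgap
Title: Actual and Normative Costing of Primary Health Care Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An activity-based costing pipeline for primary health care (PHC)
    networks. Computes actual facility-level recurrent costs allocated between
    outpatient and inpatient care with WHO-CHOICE cost-weight ratios,
    extrapolates sampled costs to the facility universe using routine
    service-volume data, builds normative costs bottom-up from standard
    treatment protocols (STPs) and populations in need at full coverage,
    derives the per-capita financial resource gap and required-investment
    multiple, and runs one-way tornado and best-/worst-case sensitivity
    analyses. Includes a synthetic-world generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
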