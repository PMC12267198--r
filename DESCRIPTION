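Package: pdl1impact
Title: Population Health Impact of Early-Stage Anti-PD-(L)1 Adoption
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Multi-state weekly-cycle cohort model projecting national
    health outcomes of making anti-PD-(L)1 immunotherapy available in the
    neoadjuvant/adjuvant setting for early-stage melanoma, renal cell
    carcinoma and triple-negative breast cancer, versus reserving it for
    advanced/metastatic disease.  Parametric survival transitions with a
    background-mortality floor, retreatment-eligibility strata, QALY and
    adverse-event accounting, scenario comparison with per-year and
    cumulative reporting, subgroup and one-way sensitivity analyses, a
    synthetic parameter generator, and an individual-level microsimulation
    cross-check of the deterministic engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    flexsurv,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
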