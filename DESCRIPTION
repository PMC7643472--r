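Package: pharmflow
Title: Stock-Flow Projection of Pharmacy Pharmacist Supply, Demand and Sufficiency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete-time system-dynamics projection of the supply of
    pharmacists working in community pharmacies, built on the career-path
    pipeline (university enrollment, six-year education, national licensure
    exam with a re-take loop, graduate school, workplace choice, regional
    allocation and attrition), together with an age-structured
    prescription-based demand projector, supply/demand sufficiency
    evaluation, a relative-RMSE backtest, one-at-a-time sensitivity sweeps
    and regional diffusion scenario analysis. Ships a deterministic
    synthetic-data generator that emulates the external population,
    prescription-rate and historical head-count inputs so the full pipeline
    runs end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
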