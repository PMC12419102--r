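Package: vtwins
Title: Virtual-Twin Causal Benchmarking of Hospital Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Patient-level causal benchmarking of binary adverse outcomes
    across hospitals (or any categorical exposure) using virtual twins.
    Per-hospital risk forests with out-of-bag counterfactual prediction
    estimate each patient's causal relative risk against a pooled
    "overall hospital" baseline; isolation-forest anomaly scores screen
    out patients without valid counterfactual support ("bad virtual
    twins"); risk-stratified summaries, standardized-beta ANOVA grading,
    and diagnostic graphics summarise institutional performance. Includes
    a synthetic multi-hospital cohort simulator with known ground truth
    for validating every stage of the pipeline.
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
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
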