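Package: flipscope
Title: Intermittent-Flow Respirometry, Recovery Metabolism and Escape
    Kinematics for Aquatic Ectotherms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to turn raw intermittent-flow respirometry oxygen traces
    and chase-video click tracks into the standard metabolic phenotyping
    trait set for aquatic ectotherms: per-cycle mass-specific oxygen
    consumption (MO2) with background correction and quality control;
    standard, routine and maximum metabolic rate; aerobic and factorial
    scope; recovery time, excess post-exercise oxygen consumption (EPOC)
    and recovery rate; Q10 thermal coefficients, acclimation contrasts and
    between-species divergence summaries; and escape speeds from
    frame-calibrated click tracks. A synthetic-data generator with known
    ground truth emulates post-exhaustion recovery trials in flush/measure
    respirometry chambers so every stage of the pipeline can be validated
    by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
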