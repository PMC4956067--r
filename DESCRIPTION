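Package: fmsdetect
Title: Rule-Based Detection of Fundamental Movement Skills in Skeleton Motion Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and counts fundamental movement skills (jumps and
    sidesteps) in 20-joint skeleton motion streams recorded by consumer
    depth sensors. Provides a data model and binary/JSONL file formats for
    skeleton streams, dual-sensor T-pose calibration and per-joint stream
    fusion, a Boolean rule language over joint-displacement conditions with
    a sliding-window matcher, a synthetic session generator with ground
    truth for validation, and the inter-rater reliability statistics used
    to evaluate automated movement counting against human raters:
    intraclass correlation ICC(2,1) with confidence intervals, percentage
    agreement, and Bland-Altman limits of agreement.
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
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
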