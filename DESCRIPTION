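Package: dentpost
Title: Post-Processing Corrections for Tooth-Instance Caries Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing stack for ordinal (ICDAS 0-6) tooth-instance
    object detection. Implements greedy and Soft non-maximum suppression over
    raw per-anchor predictions, score-weighted ordinal category correction
    with edge-class reversion, and a two-pass spatial confidence correction
    that diagnoses false-negative gaps and false-positive isolates from
    dental-arch neighbor geometry. Ships a mAP@50 evaluator (all-point
    interpolated average precision with class-aware greedy matching), a
    rank-test comparison of seed sets, and a synthetic dentition/detector
    simulator with long-tail ICDAS class priors so every correction can be
    exercised and measured without images or trained models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
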