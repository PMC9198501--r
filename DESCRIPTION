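Package: predread
Title: Language-Model Predictability Metrics for Eye Movements in Reading
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Computes word-by-word next-word predictability metrics
    (prediction entropy before a word, surprisal at the word, and
    target-prediction embedding similarity) from a pluggable causal
    language-model backend, merges them with interest-area eye-movement
    reports, cloze norms and word-frequency tables, and fits crossed
    random-intercept mixed-effects models of skipping, fixation durations
    and regression probability, including an equal-frequency-binned
    low-entropy/high-surprisal prediction-error-cost analysis. Ships a
    fully transparent table-driven toy language model and synthetic
    gaze/cloze generators so the whole pipeline is testable end to end
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    car,
    lme4,
    jsonlite,
    yaml,
    tibble,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
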