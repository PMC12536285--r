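Package: decadd
Title: Decade Effects in Serial Mental Addition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how the base-10 place-value notation shapes
    mental addition. Implements a taxonomy of addition types anchored in
    decade complements (post-complements, subcomplements, complements and
    supercomplements, plus the nine-way extension for paired addends),
    constrained generators for serial-addition stimulus lists, a generative
    simulator of participants adding digit lists (type-specific latency
    gradients, problem-size slopes, participant-level variation,
    miscalculation errors, late entries and strategic addend-order choice),
    conservative accuracy and latency measurement with outlier screening,
    and the mixed-effects inference pipeline (Tukey-adjusted pairwise
    contrasts, nested model comparisons of addition type against problem
    size) that turns trial logs into summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    lmerTest,
    emmeans,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
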