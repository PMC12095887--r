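Package: rmfaces
Title: Representational Momentum Analysis for Dynamic Emotional Faces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for probe-judgement studies of representational
    momentum with dynamic emotional faces. Provides trial-design generation for
    the 2 Emotion x 2 Avatar Sex x 2 Avatar Identity x 7 Probe factorial task,
    a generative synthetic observer with an analytic response model,
    point-of-subjective-equality and just-noticeable-difference estimation by
    scaled logistic-density fits, a transformed two-up/two-down staircase for
    ambiguity thresholds, weighted-confidence metacognition summaries, the
    mixed-design ANOVA/ANCOVA statistical layer with effect sizes, and
    simulation-based power analysis for the 2 x 2 mixed design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    png,
    jsonlite
Config/testthat/edition: 3
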