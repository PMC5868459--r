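Package: retrocue
Title: Analysis of Double-Probe Retrocueing Working-Memory Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Full analysis pipeline for continuous-report visual
    working-memory experiments in which one of four memorised orientations
    may be retrocued and two items are probed in sequence. Provides circular
    error statistics and recall accuracy (inverse circular standard
    deviation), maximum-likelihood fitting of the two-component von Mises
    plus uniform guessing mixture, sliding-bin relative-orientation bias
    curves with the area-difference attraction/repulsion statistic,
    trial-wise error trade-off correlations with Fisher transform,
    repeated-measures ANOVA with partial eta squared, default JZS Bayes
    factors for t tests, and a reproducible synthetic-cohort simulator
    emulating the experimental designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
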