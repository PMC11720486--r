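Package: awarekit
Title: Model-Based Analysis of Masked Priming and Visual Awareness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying unconscious visual processing in masked
    priming experiments that combine objective (forced-choice) and subjective
    (Perceptual Awareness Scale) measures of prime awareness. Provides a
    synthetic experiment generator with a bivariate evidence model, the
    standard trial trimming and participant exclusion rules, signal detection
    sensitivity measures (objective and subjective d'), default Bayes factors
    (JZS t tests, correlation tests, repeated-measures ANOVA with inclusion
    Bayes factors), a Bayesian measurement-error correction to the Greenwald
    regression estimating priming at chance-level awareness, and maximum
    likelihood fitting of a family of two-dimensional general recognition
    theory models with individual differences (GRT-wIND), from which
    sensitivity-versus-awareness curves with parametric bootstrap bands are
    constructed.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    rjags,
    coda,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mvtnorm,
    pracma,
    withr
Config/testthat/edition: 3
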