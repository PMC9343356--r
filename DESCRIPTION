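Package: wheelbets
Title: Simulation and Analysis of a Circular Betting Game for Probing
    Probabilistic Perception
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a continuous-report psychophysics paradigm in which
    observers place six Gaussian "bets" on a 360-degree shape wheel to draw
    an uncertainty profile over stimulus space, earning points proportional
    to the profile height at the target under a diminishing-returns stacking
    penalty.  The package implements the scoring engine (wrapped Gaussian
    components, penalty recursion, point calibration), circular error
    statistics (signed errors, circular and cumulative means, profile
    alignment), seeded generative observer models embodying competing
    theoretical accounts of perceptual representation (sampling from an
    internal distribution versus a discrete point estimate with or without
    confidence coupling), and the analysis battery that discriminates among
    them: spread-error correlations with Fisher-z aggregation,
    Kolmogorov-Smirnov comparison of first-response error distributions
    against trial-averaged uncertainty profiles (with a flipped-profile
    control), bet-order error curves with repeated-measures ANOVA, and
    undo-event summaries.  A dataset schema with CSV readers and writers and
    a small command-line interface tie simulation, scoring, and analysis
    together reproducibly.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
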