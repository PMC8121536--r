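Package: delaydisc
Title: Experiential and Hypothetical Delay Discounting Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying temporal (delay) discounting when rewards are
    experienced in the moment versus merely hypothetical. Implements the
    semi-adaptive bisection staircase that elicits indifference points on a
    fixed grid of immediate-reward levels, hyperbolic and two-parameter
    logistic discounting curves with bounded multi-start least-squares
    fitting, model-based area under the discounting curve, the linearized
    mixed-model framework (maximum likelihood, AIC/BIC, likelihood-ratio
    tests, Nakagawa-Schielzeth R-squared), perceptual reward sensitivity from
    pleasantness ratings, summary-statistic Welch tests, a default-prior
    Bayes factor for Pearson correlations, and recursive path models (with
    and without mediation) linking state and trait anxiety to discounting.
    A synthetic-agent generator emulates a full study so that every stage of
    the pipeline is testable without human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    MASS,
    pracma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
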