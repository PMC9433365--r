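Package: cmmrisk
Title: Censored Mixture Models for Sequential Risk Tasks
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits censored mixture models (CMM) to sequential risk task data such
    as the Columbia Card Task. The observed number of cards turned over is modelled
    through a latent intention following a multiple-inflated, right-censored
    negative binomial distribution with a softplus inverse link, with finite
    mixture (latent class) heterogeneity in the intercept and, optionally, in the
    game setting effects. Includes the deterministic game-mechanics kernel
    (censoring hazards, outcome probabilities, expected-value strategy tables),
    sum-to-zero covariate encoding with interactions and lagged loss-experience
    dummies, maximum likelihood estimation with delta-method standard errors,
    BIC-based segment selection, posterior segment membership, model-fit
    diagnostics (censoring-corrected predicted distributions, chi-square and
    Hellinger goodness of fit), a trial-level simulator, and a parameter-recovery
    study driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
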