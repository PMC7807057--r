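Package: hapticdyad
Title: Simulation and Analysis of Haptically Coupled Joint Perceptual
    Decisions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools to simulate and analyse two-interval forced-choice
    experiments in which pairs of observers (dyads) make individual
    perceptual decisions and, on disagreement, negotiate a joint decision
    through a coupled one degree-of-freedom haptic channel.  Provides
    cumulative-Gaussian psychometric fitting for individuals and dyads,
    closed-form dyad predictions under the Weighted Confidence Sharing
    model and alternative group-decision rules (coin flip, best member,
    direct signal sharing), leadership analyses of group-phase handle
    trajectories (first-crossing predictor, peak force, mechanical work,
    velocity ratios), cohort-level statistics, and a synthetic
    dyad-experiment generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    graphics,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
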