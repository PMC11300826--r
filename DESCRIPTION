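Package: driverlatent
Title: Latent Cognitive-Factor Inference from Driving Behavior for
    Personalized Safety Interfaces
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying when an in-vehicle warning interface (HMI)
    helps or harms an individual driver. Provides a dilemma-zone driving
    simulator whose yellow-light behavior depends on cognitive factors
    (impulsivity, inhibitory control) and HMI condition through a linear
    mixed-effects structure; a variational LSTM trajectory encoder trained
    with a contrastive loss on continuous cognitive targets; a support-vector
    regression decision model that maps latent encodings to a deploy/withhold
    HMI decision; and a leave-one-out counterfactual evaluation harness with
    embedding-separation diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    lme4
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
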