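Package: reachrc
Title: Reverse-Correlation Analysis of Random-Walk Perturbations in Reaching
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for estimating time-resolved visuomotor feedback responses
    from interception movements perturbed by random-walk jitter of either the
    target or a hand cursor. Implements the conditional-averaging (reverse
    correlation) kernel estimator on Savitzky-Golay lateral accelerations,
    backward frame synchronisation from the end of the movement, a
    through-origin comparison of cursor versus target response vigour, and a
    seeded synthetic-trial simulator with a configurable feedback-control law
    so that every analysis stage can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
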