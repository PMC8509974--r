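Package: autorbit
Title: Simulation and Motor-Learning Analysis of the Auto Orbit Paced-Shooting Task
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A tick-level simulator of the Auto Orbit video game (a spaceship
    orbiting a balloon that must be inflated by paced shots and burst by a quick
    double shot), a control-tuning cognitive agent built from bounded-parameter
    trackers sampled by a softmax over a quadratic payoff estimate with an
    annealed temperature, a pacemaker-accumulator interval clock, and the
    behavioral analysis pipeline for skill-transfer experiments across game
    speeds: performance counts, keypress-triple Shannon entropy, log coefficient
    of variation of inter-shot intervals, autocorrelation-based shot periodicity
    and regularity, percent transfer with bootstrap resampling, and RMSE/BIC
    model comparison.
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
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
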