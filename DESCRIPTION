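Package: spsgame
Title: Multi-Agent Q-Learning for the Sir Philip Sidney Signalling Game
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates the Sir Philip Sidney signalling game between two
    tabular Q-learning agents rewarded by inclusive fitness. Provides the
    game's survival payoffs, signal costs and inclusive-fitness matrices,
    the analytic relatedness threshold predicting the donor's equilibrium
    action, epsilon-greedy learning agents with configurable memory and
    exploration schedules, a fully seeded dyadic experiment harness, a
    periodic strategy-cycle classifier, and replication presets with
    learning-rate and discount-rate sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
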