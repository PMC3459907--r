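Package: popgrad
Title: Spiking Population Reinforcement Learning of Nash Equilibria in
    Two-Player Games
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates decision learning in repeated two-player games by a
    population of stochastically spiking neurons whose synapses follow a
    reward-modulated policy-gradient rule (population reinforcement
    learning), together with the comparison learners commonly used in
    neuroeconomics: a population covariance rule with binary neurons,
    SARSA temporal-difference learning with a softmax policy, and the
    Roth-Erev basic reinforcement models. Provides the two game
    environments (a simplified blackjack played against the bank, and the
    inspector game) with exact analytic solvers for the stopping-value
    distributions, the expected payoff matrix, its saddle point (pure
    Nash equilibrium), and the mixed Nash equilibrium of the 2x2 bimatrix
    game, plus orchestration of learner-vs-learner matches and
    running-rate analytics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
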