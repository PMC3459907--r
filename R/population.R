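#' Population and decision-readout configuration
#'
#' @param n_neurons Population size \eqn{N}.
#' @param connect_prob Probability that a population neuron receives a given
#'   afferent; absent synapses carry weight exactly 0 and are never updated.
#' @param readout_scale Slope parameter \eqn{\lambda} of the decision
#'   sigmoid. The sigmoid argument is \eqn{(A - N/2)/(\lambda\sqrt N)}:
#'   centering at \eqn{N/2} and scaling by \eqn{\sqrt N} keeps it of the
#'   same order as the binomial fluctuations of the population activity.
#' @return An object of class `population_config`.
#' @export
population_config <- function(n_neurons = 50, connect_prob = 0.5,
                              readout_scale = 1) {
  if (n_neurons < 1) stop_invalid("n_neurons must be >= 1")
  if (connect_prob <= 0 || connect_prob > 1)
    stop_invalid("connect_prob must be in (0, 1]")
  if (readout_scale <= 0) stop_invalid("readout_scale must be positive")
  structure(list(n_neurons = as.integer(n_neurons),
                 connect_prob = connect_prob,
                 readout_scale = readout_scale),
            class = "population_config")
}

#' Population activity
#'
#' Number of neurons that emitted at least one output spike (spike/no-spike
#' code \eqn{\sigma_i \in \{0,1\}}, \eqn{A = \sum_i \sigma_i}).
#'
#' @param trains A list of [spike_train()] objects, or a 0/1 vector of
#'   per-neuron spike indicators.
#' @return Integer activity \eqn{A}.
#' @export
population_activity <- function(trains) {
  if (!length(trains)) stop_invalid("empty population")
  sigma <- if (is.list(trains)) {
    vapply(trains, function(tr) as.integer(tr$fired), integer(1))
  } else as.integer(trains != 0)
  sum(sigma)
}

check_activity <- function(A, cfg) {
  if (A < 0 || A > cfg$n_neurons)
    stop_invalid("activity A must lie in [0, N]")
}

#' Probability of the behavioral decision D = 1
#'
#' Logistic readout of the population activity:
#' \deqn{P(D=1\mid A) = \frac{1}{1 + \exp(-(A - N/2)/(\lambda\sqrt N))},}
#' strictly increasing in \eqn{A}.
#'
#' @param A Population activity in `[0, N]` (integer, or real-valued for
#'   analytic checks).
#' @param cfg A [population_config()].
#' @return Probability in (0, 1).
#' @export
#' @examples
#' decision_prob(1, population_config(n_neurons = 1))  # ~0.6225
decision_prob <- function(A, cfg) {
  check_activity(A, cfg)
  N <- cfg$n_neurons
  plogis((A - N / 2) / (cfg$readout_scale * sqrt(N)))
}

#' Decision-feedback factor f'
#'
#' Sensitivity of the decision log-probability to the population activity,
#' \eqn{f' = \partial \log P(D\mid A)/\partial A = (D - p)/(\lambda\sqrt N)}
#' with \eqn{p = P(D=1\mid A)}. This single scalar is broadcast to every
#' synapse as the population-level credit signal; its mean over
#' \eqn{D \sim P(\cdot\mid A)} is exactly zero (score function).
#'
#' @param D Behavioral decision, 0 or 1.
#' @param A Population activity.
#' @param cfg A [population_config()].
#' @return The scalar \eqn{f'}; positive when `D == 1`, negative otherwise.
#' @export
decision_feedback <- function(D, A, cfg) {
  if (!D %in% c(0, 1)) stop_invalid("D must be 0 or 1")
  p <- decision_prob(A, cfg)
  (D - p) / (cfg$readout_scale * sqrt(cfg$n_neurons))
}

#' Sample a Bernoulli decision
#'
#' @param p Probability of decision 1, in (0, 1).
#' @param seed Optional integer seed.
#' @return 0 or 1.
#' @export
sample_decision <- function(p, seed = NULL) {
  if (p <= 0 || p >= 1) stop_invalid("p must be in (0, 1)")
  with_seed(seed, as.integer(runif(1) < p))
}
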