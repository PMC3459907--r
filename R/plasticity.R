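#' Learning-rule configuration
#'
#' @param eta Learning rate of the population policy-gradient rule (> 0);
#'   absorbed into the reward signal \eqn{R' = \eta(R - \bar R)}.
#' @param gamma_rbar Update rate of the running mean reward estimate
#'   \eqn{\bar R}, in (0, 1].
#' @param rbar_scope `"per_state"` (one \eqn{\bar R} per stimulus, so the
#'   reward factor averages to zero for each stimulus individually) or
#'   `"global"`; the two coincide for a single-state game such as the
#'   inspector game.
#' @param neg_term_factor Multiplier on the negative (membrane-potential)
#'   term of the eligibility trace. 1 gives the exact log-likelihood
#'   gradient; 2 or 0 are the perturbed variants used in robustness checks
#'   (0 leaves pre-post spike pairing only).
#' @param nu Learning rate of the population covariance rule (> 0).
#' @param rbar_init Initial value of \eqn{\bar R} on the first visit of a
#'   state.
#' @return An object of class `learn_config`.
#' @export
learn_config <- function(eta = 0.05, gamma_rbar = 0.05,
                         rbar_scope = c("per_state", "global"),
                         neg_term_factor = 1, nu = 0.05, rbar_init = 0) {
  rbar_scope <- match.arg(rbar_scope)
  if (eta <= 0) stop_invalid("eta must be positive")
  if (gamma_rbar <= 0 || gamma_rbar > 1)
    stop_invalid("gamma_rbar must be in (0, 1]")
  if (neg_term_factor < 0) stop_invalid("neg_term_factor must be >= 0")
  if (nu <= 0) stop_invalid("nu must be positive")
  structure(list(eta = eta, gamma_rbar = gamma_rbar,
                 rbar_scope = rbar_scope,
                 neg_term_factor = neg_term_factor, nu = nu,
                 rbar_init = rbar_init),
            class = "learn_config")
}

#' Synaptic eligibility trace of one neuron
#'
#' Per-afferent accumulator of the log-likelihood gradient of the emitted
#' spike train. For the exponential escape rate,
#' \deqn{e_j = \frac{1}{\Delta u}\Big[\sum_{t^f} \mathrm{PSP}_j(t^f)
#'   - c\sum_t \rho(u(t))\,\mathrm{PSP}_j(t)\,dt\Big],}
#' where \eqn{c} is `cfg$neg_term_factor`. With \eqn{c = 1} this equals
#' \eqn{\partial \log P(y)/\partial w_j} of [log_likelihood()] (density
#' form) exactly, and its expectation over outputs sampled from the model
#' is zero: the positive spike-timing term and the negative potential term
#' balance on average.
#'
#' @param psp PSP matrix (afferents x grid steps) of the input pattern.
#' @param output Output [spike_train()], numeric spike times (ms), or a
#'   vector of 1-based grid step indices (`integer`).
#' @param u Membrane-potential trace on the same grid (including resets
#'   from the output).
#' @param escape An [escape_params()].
#' @param cfg A [learn_config()].
#' @return Numeric vector \eqn{e_j}, one entry per afferent.
#' @export
eligibility_trace <- function(psp, output, u, escape, cfg = learn_config()) {
  if (length(u) != ncol(psp))
    stop_invalid("membrane trace and PSP grid lengths differ")
  steps <- if (is.integer(output)) output
           else {
             times <- if (inherits(output, "spike_train")) output$spikes
                      else as.numeric(output)
             round(times / escape$dt) + 1L
           }
  if (any(steps < 1L | steps > ncol(psp)))
    stop_invalid("output spike outside the grid")
  rho <- escape_rate(u, escape)
  pos <- if (length(steps)) rowSums(psp[, steps, drop = FALSE]) else 0
  neg <- as.vector(psp %*% (rho * escape$dt))
  (pos - cfg$neg_term_factor * neg) / escape$delta_u
}

#' Running mean reward estimator
#'
#' @param init Initial estimate used on the first visit of each state.
#' @return An object of class `reward_estimator` holding one running mean
#'   per state key.
#' @export
reward_estimator <- function(init = 0) {
  structure(list(rbar = numeric(0), init = init), class = "reward_estimator")
}

#' Reward prediction error
#'
#' Computes \eqn{R' = \eta (R - \bar R_{s})} and then updates the running
#' mean for the visited state,
#' \eqn{\bar R_s \leftarrow (1 - \gamma)\bar R_s + \gamma R}. The first
#' visit of a state initializes \eqn{\bar R_s} to the estimator's prior.
#'
#' @param R Delivered reward (finite scalar).
#' @param state_key Character key of the stimulus/state (ignored for
#'   `rbar_scope = "global"`).
#' @param est A [reward_estimator()].
#' @param cfg A [learn_config()].
#' @return A list with `rprime` (the scaled prediction error) and
#'   `estimator` (the updated estimator).
#' @export
reward_prediction_error <- function(R, state_key, est, cfg = learn_config()) {
  if (!is.finite(R)) stop_invalid("reward must be finite")
  key <- if (cfg$rbar_scope == "global") ".global" else as.character(state_key)
  rbar <- if (key %in% names(est$rbar)) est$rbar[[key]] else est$init
  rprime <- cfg$eta * (R - rbar)
  est$rbar[[key]] <- (1 - cfg$gamma_rbar) * rbar + cfg$gamma_rbar * R
  list(rprime = rprime, estimator = est)
}

#' Population policy-gradient weight update
#'
#' Applies the four-factor rule
#' \deqn{w_{ij} \leftarrow w_{ij} + \sum_d R'_d\, f'_d\, \sigma_{i,d}\,
#'   e_{ij,d}:}
#' reward prediction error, decision feedback, single-neuron decision and
#' eligibility trace, summed over the decision periods of the episode.
#' Masked-out synapses stay at exactly zero.
#'
#' @param weights Weight matrix (neurons x afferents), optionally with a
#'   0/1 `mask` attribute of the same shape.
#' @param episode A list of per-decision records, each a list with `fprime`
#'   (scalar), `sigma` (0/1 vector, one per neuron) and `elig` (matrix,
#'   neurons x afferents).
#' @param rprime Scalar \eqn{R'} applied to every decision period, or a
#'   vector with one entry per decision (used with per-state reward means,
#'   where \eqn{\bar R} differs across the hand values visited in one
#'   blackjack episode).
#' @return The updated weight matrix.
#' @export
prl_update <- function(weights, episode, rprime) {
  if (!length(episode)) stop_invalid("episode contains no decision records")
  if (!length(rprime) %in% c(1L, length(episode)))
    stop_invalid("rprime must be scalar or one value per decision")
  rprime <- rep_len(rprime, length(episode))
  delta <- 0
  for (d in seq_along(episode)) {
    rec <- episode[[d]]
    if (is.null(rec$fprime) || is.null(rec$sigma) || is.null(rec$elig))
      stop_invalid("invalid episode: each record needs fprime, sigma, elig")
    if (!identical(dim(rec$elig), dim(weights)))
      stop_invalid("eligibility dimensions do not match the weights")
    delta <- delta + rprime[d] * rec$fprime * (rec$sigma * rec$elig)
  }
  w <- weights + delta
  mask <- attr(weights, "mask")
  if (!is.null(mask)) {
    w <- w * mask
    attr(w, "mask") <- mask
  }
  w
}

#' Forward pass of a stochastic binary neuron
#'
#' The reduced neuron model used by the covariance rule: for a binary input
#' pattern the neuron fires (\eqn{\sigma = 1}) with probability
#' \eqn{\langle\sigma\rangle = g(w \cdot x)}, \eqn{g} the logistic function.
#'
#' @param weights Numeric weight vector.
#' @param x Input vector, entries in `{0, 1}` (or `{-1, +1}` under the
#'   symmetric coding variant).
#' @param seed Optional integer seed.
#' @return A list with `sigma` (0/1 sample) and `sigma_mean`
#'   (\eqn{g(w\cdot x)}).
#' @export
binary_forward <- function(weights, x, seed = NULL) {
  m <- plogis(sum(weights * x))
  list(sigma = with_seed(seed, as.integer(runif(1) < m)), sigma_mean = m)
}

#' Population covariance (pCOV) weight update
#'
#' Replaces the eligibility trace of the gradient rule by the deviation of
#' the neuronal response from a center:
#' \deqn{w_j \leftarrow w_j + \nu\, R'\, f'(D, A)\,
#'   (\sigma - \bar\sigma)\, x_j.}
#' The center may be the analytic mean \eqn{g(w\cdot x)}, a running
#' average, or 0 (the no-subtraction variant). This rule does not follow
#' the reward gradient.
#'
#' @param weights Weight vector of one binary neuron.
#' @param x Binary input vector.
#' @param sigma The neuron's 0/1 response.
#' @param sigma_center The subtracted response center (see Details).
#' @param D,A Behavioral decision and population activity of the trial.
#' @param rprime Reward prediction error \eqn{R - \bar R}.
#' @param cfg A [learn_config()] (supplies \eqn{\nu}).
#' @param pop A [population_config()] (supplies the decision feedback).
#' @return The updated weight vector.
#' @export
pcov_update <- function(weights, x, sigma, sigma_center, D, A, rprime,
                        cfg = learn_config(), pop = population_config()) {
  fp <- decision_feedback(D, A, pop)
  weights + cfg$nu * rprime * fp * (sigma - sigma_center) * x
}
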