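#' Softmax action-selection probabilities
#'
#' \eqn{p_a \propto \exp(\beta q_a)}, computed with max-subtraction for
#' numerical stability.
#'
#' @param qvalues Numeric vector of action values (>= 2 actions).
#' @param beta Inverse temperature (> 0).
#' @return Probability vector summing to 1.
#' @export
#' @examples
#' softmax_policy(c(1, 0), beta = 1)  # ~ (0.7311, 0.2689)
softmax_policy <- function(qvalues, beta) {
  if (length(qvalues) < 2) stop_invalid("need at least two actions")
  if (beta <= 0) stop_invalid("beta must be positive")
  z <- beta * (qvalues - max(qvalues))
  e <- exp(z)
  e / sum(e)
}

#' State-action value table for SARSA
#'
#' @param alpha Learning rate in (0, 1].
#' @param beta Softmax inverse temperature (> 0).
#' @return An object of class `q_table`; unvisited pairs default to value 0.
#' @export
q_table <- function(alpha = 0.1, beta = 3) {
  if (alpha <= 0 || alpha > 1) stop_invalid("alpha must be in (0, 1]")
  if (beta <= 0) stop_invalid("beta must be positive")
  structure(list(q = numeric(0), alpha = alpha, beta = beta),
            class = "q_table")
}

q_key <- function(s, a) paste(s, a, sep = "|")

#' Look up a state-action value
#'
#' @param tab A [q_table()].
#' @param s,a State and action keys.
#' @return The stored value, or 0 if the pair was never visited.
#' @export
q_value <- function(tab, s, a) {
  k <- q_key(s, a)
  if (k %in% names(tab$q)) tab$q[[k]] else 0
}

#' SARSA update (undiscounted, episodic)
#'
#' \deqn{Q(s,a) \leftarrow Q(s,a) + \alpha\,(r + Q(s',a')\,[\neg terminal]
#'   - Q(s,a)).}
#'
#' @param tab A [q_table()].
#' @param s,a Current state and action.
#' @param r Immediate reward.
#' @param s_next,a_next Next state and action (ignored when `terminal`).
#' @param terminal Logical; TRUE if the episode ends after this transition.
#' @return The updated table.
#' @export
sarsa_update <- function(tab, s, a, r, s_next = NULL, a_next = NULL,
                         terminal = FALSE) {
  target <- r + if (terminal) 0 else q_value(tab, s_next, a_next)
  k <- q_key(s, a)
  tab$q[[k]] <- q_value(tab, s, a) + tab$alpha * (target - q_value(tab, s, a))
  tab
}

#' Initial propensities for the Roth-Erev models
#'
#' Each action starts with propensity \eqn{q_k = s(1)\,\bar X}, where
#' \eqn{\bar X} is the player's average payoff when both sides choose
#' uniformly at random and \eqn{s(1)} is the strength parameter.
#'
#' @param payoffs The player's own payoff matrix (rows = own actions,
#'   columns = opponent actions) or a vector of payoff cells.
#' @param strength Strength parameter \eqn{s(1) > 0}.
#' @param n_actions Number of own actions.
#' @param eps_gen Generalization parameter in `[0, 1)` (RE3).
#' @param phi Forgetting parameter in `[0, 1)` (RE3).
#' @param floor Small positive floor applied (with a warning) if the mean
#'   payoff is not positive, so that choice probabilities stay defined.
#' @return An object of class `propensity_vector`.
#' @export
re_init <- function(payoffs, strength, n_actions = 2, eps_gen = 0, phi = 0,
                    floor = 1e-6) {
  if (strength <= 0) stop_invalid("strength must be positive")
  if (eps_gen < 0 || eps_gen >= 1) stop_invalid("eps_gen must be in [0, 1)")
  if (phi < 0 || phi >= 1) stop_invalid("phi must be in [0, 1)")
  xbar <- mean(as.numeric(payoffs))
  q0 <- strength * xbar
  if (q0 <= 0) {
    warning("non-positive mean payoff; flooring initial propensities at ",
            floor)
    q0 <- floor
  }
  structure(list(q = rep(q0, n_actions), strength = strength,
                 eps_gen = eps_gen, phi = phi, floor = floor),
            class = "propensity_vector")
}

#' Choice probabilities of a propensity vector
#'
#' @param pv A [re_init()] object.
#' @return \eqn{q_k / \sum_l q_l}.
#' @export
re_probs <- function(pv) pv$q / sum(pv$q)

#' Basic Roth-Erev update (RE1)
#'
#' The propensity of the chosen action is incremented by the received
#' reward; the others are unchanged.
#'
#' @param pv A [re_init()] object.
#' @param action Chosen action index (1-based).
#' @param reward Received reward.
#' @return The updated propensity vector.
#' @export
re1_update <- function(pv, action, reward) {
  pv$q[action] <- pv$q[action] + reward
  pv
}

#' Roth-Erev update with generalization and forgetting (RE3)
#'
#' \deqn{q_j \leftarrow (1-\phi) q_j + r\,(1-\varepsilon) \quad (j = a),
#'   \qquad q_j \leftarrow (1-\phi) q_j + r\,\varepsilon \quad (j \ne a),}
#' the two-action form; with \eqn{\phi = \varepsilon = 0} it reduces to
#' RE1.
#'
#' @inheritParams re1_update
#' @return The updated propensity vector.
#' @export
re3_update <- function(pv, action, reward) {
  n <- length(pv$q)
  spread <- if (n > 1) pv$eps_gen / (n - 1) else 0
  inc <- rep(reward * spread, n)
  inc[action] <- reward * (1 - pv$eps_gen)
  pv$q <- (1 - pv$phi) * pv$q + inc
  pv
}
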