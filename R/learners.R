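#' Learner interface
#'
#' All learners expose the same two generics so matches can be orchestrated
#' learner-agnostically: [act()] returns a binary action for a named game
#' state (1 = draw / shirk / inspect depending on the role), buffering
#' whatever the learner needs for credit assignment, and [give_reward()]
#' closes the episode by applying the learner's update with the terminal
#' reward. Learners are environments, so updates persist across calls.
#'
#' @param learner A learner object.
#' @param state Character key of the current game state.
#' @param reward Terminal reward of the episode.
#' @name learner-interface
NULL

#' @rdname learner-interface
#' @return `act()`: integer 0/1 action.
#' @export
act <- function(learner, state) UseMethod("act")

#' @rdname learner-interface
#' @return `give_reward()`: the learner, invisibly.
#' @export
give_reward <- function(learner, reward) UseMethod("give_reward")

new_learner <- function(class, fields) {
  e <- new.env(parent = emptyenv())
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  class(e) <- c(class, "learner")
  e
}

#' @export
print.learner <- function(x, ...) {
  cat(sprintf("<%s learner, states: %s>\n", class(x)[1],
              paste(x$states, collapse = ", ")))
  invisible(x)
}

#' Spiking population policy-gradient learner
#'
#' A population of spike-response neurons with escape noise whose synapses
#' follow the four-factor reward-gradient rule (reward prediction error,
#' decision feedback, neuronal decision, eligibility trace). Each game
#' state is encoded by its own frozen Poisson spike pattern, generated once
#' from seeds derived from `seed`; initial weights are Gaussian with mean 0
#' on a Bernoulli connectivity mask.
#'
#' @param states Character vector of game-state keys the learner can face.
#' @param n_channels Afferents per input pattern.
#' @param pattern_rate Poisson rate of the frozen patterns (Hz).
#' @param duration Pattern duration (ms).
#' @param kernels,escape,pop,cfg Model configurations
#'   ([kernel_params()], [escape_params()], [population_config()],
#'   [learn_config()]).
#' @param weight_sd Standard deviation of the initial Gaussian weights.
#' @param seed Integer seed for patterns, mask and initial weights.
#' @return A `prl_learner`.
#' @details If `kernels` is not supplied, the resting potential is set to
#'   \eqn{u_{rest} = \theta + \Delta u \log(\log 2 / (\rho_0 T))} so that a
#'   neuron with zero-mean initial weights fires at least one spike with
#'   probability about 1/2. This puts the initial population activity near
#'   \eqn{N/2} and hence the initial choice behavior near the random 50/50
#'   prior assumed before learning.
#' @export
learner_prl <- function(states, n_channels = 100, pattern_rate = 6,
                        duration = 500, kernels = NULL,
                        escape = escape_params(),
                        pop = population_config(), cfg = learn_config(),
                        weight_sd = 0.1, seed = 1) {
  if (is.null(kernels)) {
    kernels <- kernel_params(
      u_rest = escape$theta +
        escape$delta_u * log(log(2) / (escape$rho0 * duration)))
  }
  states <- as.character(states)
  patterns <- lapply(seq_along(states), function(k) {
    generate_frozen_pattern(n_channels, pattern_rate, duration,
                            seed = derive_seed(seed, paste0("pattern", k)),
                            pattern_id = states[k])
  })
  names(patterns) <- states
  psps <- lapply(patterns, psp_matrix, kernels = kernels, escape = escape)
  N <- pop$n_neurons
  mask <- with_seed(derive_seed(seed, "mask"), {
    matrix(rbinom(N * n_channels, 1, pop$connect_prob), N, n_channels)
  })
  weights <- with_seed(derive_seed(seed, "weights"), {
    matrix(rnorm(N * n_channels, 0, weight_sd), N, n_channels)
  }) * mask
  attr(weights, "mask") <- mask
  new_learner("prl_learner", list(
    states = states, patterns = patterns, psps = psps,
    kernels = kernels, escape = escape, pop = pop, cfg = cfg,
    weights = weights, estimator = reward_estimator(cfg$rbar_init),
    episode = list()))
}

#' @export
act.prl_learner <- function(learner, state) {
  state <- as.character(state)
  if (!state %in% learner$states) stop_invalid("unknown state: ", state)
  psp <- learner$psps[[state]]
  pattern <- learner$patterns[[state]]
  N <- learner$pop$n_neurons
  sigma <- integer(N)
  elig <- matrix(0, N, nrow(psp))
  for (i in seq_len(N)) {
    sim <- simulate_neuron(learner$weights[i, ], pattern, learner$kernels,
                           learner$escape, psp = psp)
    sigma[i] <- sim$train$fired
    elig[i, ] <- eligibility_trace(psp, sim$spike_steps, sim$u,
                                   learner$escape, learner$cfg)
  }
  A <- sum(sigma)
  p <- decision_prob(A, learner$pop)
  D <- sample_decision(p)
  learner$episode[[length(learner$episode) + 1L]] <- list(
    state = state, sigma = sigma, elig = elig, activity = A, p_one = p,
    decision = D, fprime = decision_feedback(D, A, learner$pop))
  D
}

#' @export
give_reward.prl_learner <- function(learner, reward) {
  if (!length(learner$episode)) return(invisible(learner))
  rprime <- numeric(length(learner$episode))
  for (d in seq_along(learner$episode)) {
    rpe <- reward_prediction_error(reward, learner$episode[[d]]$state,
                                   learner$estimator, learner$cfg)
    rprime[d] <- rpe$rprime
    learner$estimator <- rpe$estimator
  }
  learner$weights <- prl_update(learner$weights, learner$episode, rprime)
  learner$episode <- list()
  invisible(learner)
}

#' Population covariance learner with binary neurons
#'
#' The reduced (non-spiking) population used to study covariance learning:
#' binary neurons respond to a frozen binary input pattern per state, the
#' same activity readout makes the decision, and weights move by the
#' covariance rule of [pcov_update()].
#'
#' @inheritParams learner_prl
#' @param n_inputs Input dimensionality.
#' @param coding `"binary"` ({0,1} inputs) or `"pm1"` ({-1,+1} inputs, the
#'   variant with a provably positive effective learning rate).
#' @param center Response center subtracted in the update: the `"analytic"`
#'   mean \eqn{g(w\cdot x)}, a `"running"` average of the responses, or
#'   `"none"`.
#' @return A `pcov_learner`.
#' @export
learner_pcov <- function(states, n_inputs = 50, pop = population_config(),
                         cfg = learn_config(),
                         coding = c("binary", "pm1"),
                         center = c("analytic", "running", "none"),
                         weight_sd = 0.1, seed = 1) {
  coding <- match.arg(coding)
  center <- match.arg(center)
  states <- as.character(states)
  inputs <- lapply(seq_along(states), function(k) {
    x <- with_seed(derive_seed(seed, paste0("input", k)),
                   rbinom(n_inputs, 1, 0.5))
    if (coding == "pm1") 2 * x - 1 else x
  })
  names(inputs) <- states
  N <- pop$n_neurons
  weights <- with_seed(derive_seed(seed, "weights"),
                       matrix(rnorm(N * n_inputs, 0, weight_sd), N, n_inputs))
  new_learner("pcov_learner", list(
    states = states, inputs = inputs, pop = pop, cfg = cfg,
    weights = weights, center = center,
    run_mean = matrix(0.5, N, length(states),
                      dimnames = list(NULL, states)),
    estimator = reward_estimator(cfg$rbar_init), episode = list()))
}

#' @export
act.pcov_learner <- function(learner, state) {
  state <- as.character(state)
  if (!state %in% learner$states) stop_invalid("unknown state: ", state)
  x <- learner$inputs[[state]]
  m <- plogis(as.vector(learner$weights %*% x))
  sigma <- as.integer(runif(length(m)) < m)
  A <- sum(sigma)
  p <- decision_prob(A, learner$pop)
  D <- sample_decision(p)
  learner$episode[[length(learner$episode) + 1L]] <- list(
    state = state, x = x, sigma = sigma, sigma_mean = m, activity = A,
    decision = D, fprime = decision_feedback(D, A, learner$pop))
  D
}

#' @export
give_reward.pcov_learner <- function(learner, reward) {
  for (rec in learner$episode) {
    rpe <- reward_prediction_error(reward, rec$state, learner$estimator,
                                   learner$cfg)
    learner$estimator <- rpe$estimator
    rprime <- rpe$rprime / learner$cfg$eta  # pCOV uses nu, not eta
    centers <- switch(learner$center,
      analytic = rec$sigma_mean,
      running = learner$run_mean[, rec$state],
      none = 0)
    dev <- rec$sigma - centers
    learner$weights <- learner$weights +
      learner$cfg$nu * rprime * rec$fprime * (dev %o% rec$x)
    if (learner$center == "running") {
      g <- learner$cfg$gamma_rbar
      learner$run_mean[, rec$state] <-
        (1 - g) * learner$run_mean[, rec$state] + g * rec$sigma
    }
  }
  learner$episode <- list()
  invisible(learner)
}

#' SARSA temporal-difference learner with softmax policy
#'
#' Undiscounted episodic SARSA over (state, action) pairs with softmax
#' action selection; intermediate decisions within an episode receive
#' reward 0 and the terminal reward enters the last transition.
#'
#' @param alpha Learning rate in (0, 1].
#' @param beta Softmax inverse temperature.
#' @return A `td_learner`.
#' @export
learner_td <- function(alpha = 0.1, beta = 3) {
  new_learner("td_learner", list(tab = q_table(alpha, beta),
                                 states = "*", episode = list()))
}

#' @export
act.td_learner <- function(learner, state) {
  state <- as.character(state)
  q <- c(q_value(learner$tab, state, 0), q_value(learner$tab, state, 1))
  probs <- softmax_policy(q, learner$tab$beta)
  a <- as.integer(runif(1) < probs[2])
  learner$episode[[length(learner$episode) + 1L]] <- list(state = state,
                                                          action = a)
  a
}

#' @export
give_reward.td_learner <- function(learner, reward) {
  ep <- learner$episode
  k <- length(ep)
  if (!k) return(invisible(learner))
  for (d in seq_len(k)) {
    terminal <- d == k
    learner$tab <- sarsa_update(
      learner$tab, ep[[d]]$state, ep[[d]]$action,
      r = if (terminal) reward else 0,
      s_next = if (terminal) NULL else ep[[d + 1]]$state,
      a_next = if (terminal) NULL else ep[[d + 1]]$action,
      terminal = terminal)
  }
  learner$episode <- list()
  invisible(learner)
}

#' Roth-Erev basic reinforcement learner
#'
#' Propensity-based choice: action `k` is played with probability
#' \eqn{q_k/\sum_l q_l}. `type = "re1"` increments the chosen action's
#' propensity by the received reward; `type = "re3"` adds generalization
#' (`eps_gen`) and forgetting (`phi`).
#'
#' @param payoffs The player's own payoff cells, used to set the initial
#'   propensities to `strength` times the mean payoff under uniform play.
#' @param strength Strength parameter \eqn{s(1)}.
#' @param type `"re1"` or `"re3"`.
#' @param eps_gen,phi RE3 generalization and forgetting parameters.
#' @return An `re_learner` (propensities are kept per state).
#' @export
learner_re <- function(payoffs, strength = 1, type = c("re1", "re3"),
                       eps_gen = 0.05, phi = 0.05) {
  type <- match.arg(type)
  if (type == "re1") { eps_gen <- 0; phi <- 0 }
  new_learner("re_learner", list(
    proto = re_init(payoffs, strength, n_actions = 2, eps_gen = eps_gen,
                    phi = phi),
    type = type, pvs = list(), states = "*", episode = list()))
}

#' @export
act.re_learner <- function(learner, state) {
  state <- as.character(state)
  if (is.null(learner$pvs[[state]])) learner$pvs[[state]] <- learner$proto
  probs <- re_probs(learner$pvs[[state]])
  a <- as.integer(runif(1) < probs[2])
  learner$episode[[length(learner$episode) + 1L]] <- list(state = state,
                                                          action = a)
  a
}

#' @export
give_reward.re_learner <- function(learner, reward) {
  upd <- if (learner$type == "re1") re1_update else re3_update
  for (rec in learner$episode) {
    learner$pvs[[rec$state]] <- upd(learner$pvs[[rec$state]],
                                    rec$action + 1L, reward)
  }
  learner$episode <- list()
  invisible(learner)
}

#' Fixed (non-learning) strategy
#'
#' Either a fixed stopping value for blackjack (`threshold`: draw while the
#' hand is below it) or a fixed mixing probability of action 1
#' (`p`, e.g. a Nash-mixing inspector who inspects with probability 1/2).
#'
#' @param p Probability of action 1.
#' @param threshold Stopping value; takes precedence if given.
#' @return A `fixed_learner`.
#' @export
learner_fixed <- function(p = NULL, threshold = NULL) {
  if (is.null(p) && is.null(threshold))
    stop_invalid("give either p or threshold")
  new_learner("fixed_learner", list(p = p, threshold = threshold,
                                    states = "*"))
}

#' @export
act.fixed_learner <- function(learner, state) {
  if (!is.null(learner$threshold))
    return(as.integer(as.numeric(state) < learner$threshold))
  as.integer(runif(1) < learner$p)
}

#' @export
give_reward.fixed_learner <- function(learner, reward) invisible(learner)
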