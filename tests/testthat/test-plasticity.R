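test_that("eligibility trace equals the log-likelihood weight gradient", {
  k <- toy_kernels()
  e <- toy_escape()
  pat <- toy_pattern()
  psp <- popgrad:::psp_matrix(pat, k, e)
  w <- c(0.4, -0.2, 0.3)
  out <- c(5, 12)
  drive <- k$u_rest + as.vector(w %*% psp)
  u <- popgrad:::clamped_potential(drive, round(out / e$dt) + 1L, k, e)
  el <- eligibility_trace(psp, out, u, e)

  h <- 1e-5
  fd <- vapply(1:3, function(j) {
    wp <- w; wm <- w
    wp[j] <- wp[j] + h; wm[j] <- wm[j] - h
    (log_likelihood(wp, pat, out, k, e, psp = psp) -
       log_likelihood(wm, pat, out, k, e, psp = psp)) / (2 * h)
  }, numeric(1))
  expect_equal(el, fd, tolerance = 1e-6)

  # a channel without input spikes has zero eligibility
  pat0 <- manual_pattern(list(numeric(0), 3), duration = 20)
  psp0 <- popgrad:::psp_matrix(pat0, k, e)
  el0 <- eligibility_trace(psp0, 10, rep(0.2, 20), e)
  expect_identical(el0[1], 0)

  # the perturbed variants scale only the negative term
  el2 <- eligibility_trace(psp, out, u, e,
                           learn_config(neg_term_factor = 2))
  el_none <- eligibility_trace(psp, out, u, e,
                               learn_config(neg_term_factor = 0))
  expect_equal(el_none - el, el - el2, tolerance = 1e-12)
  expect_error(eligibility_trace(psp, out, rep(0, 5), e), "grid")
})

test_that("eligibility is zero on average under model sampling", {
  k <- toy_kernels()
  e <- toy_escape(rho0 = 0.01)  # keep the Bernoulli/density gap small
  pat <- toy_pattern()
  psp <- popgrad:::psp_matrix(pat, k, e)
  w <- c(0.3, 0.1, -0.2)
  set.seed(8)
  n <- 1e4
  es <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    s <- simulate_neuron(w, pat, k, e, psp = psp)
    es[i, ] <- eligibility_trace(psp, s$spike_steps, s$u, e)
  }
  m <- colMeans(es)
  se <- apply(es, 2, stats::sd) / sqrt(n)
  expect_true(all(abs(m) < 3 * pmax(se, 1e-12)))
})

test_that("reward prediction error tracks a per-state running mean", {
  cfg <- learn_config(eta = 0.1, gamma_rbar = 0.2)
  est <- reward_estimator()
  r1 <- reward_prediction_error(1, "s1", est, cfg)
  expect_equal(r1$rprime, 0.1)                      # eta * (1 - 0)
  expect_equal(r1$estimator$rbar[["s1"]], 0.2)

  # constant rewards: rbar -> c geometrically, rprime -> 0
  est <- reward_estimator()
  for (i in 1:60) {
    out <- reward_prediction_error(2, "s", est, cfg)
    est <- out$estimator
  }
  expect_equal(est$rbar[["s"]], 2, tolerance = 1e-4)
  expect_equal(reward_prediction_error(2, "s", est, cfg)$rprime, 0,
               tolerance = 1e-4)

  # states are tracked independently
  est <- reward_estimator()
  est <- reward_prediction_error(1, "a", est, cfg)$estimator
  expect_equal(reward_prediction_error(0, "b", est, cfg)$rprime, 0)

  # global scope ignores the key
  cfg_g <- learn_config(eta = 0.1, gamma_rbar = 0.2, rbar_scope = "global")
  est <- reward_prediction_error(1, "a", reward_estimator(), cfg_g)$estimator
  expect_equal(reward_prediction_error(1, "b", est, cfg_g)$rprime,
               0.1 * (1 - 0.2))

  # unbiasedness: long-run mean of (R - rbar) vanishes for i.i.d. rewards
  set.seed(3)
  est <- reward_estimator()
  resid <- numeric(4000)
  for (i in seq_along(resid)) {
    R <- rnorm(1, mean = 0.7)
    out <- reward_prediction_error(R, "s", est, learn_config(eta = 1))
    resid[i] <- out$rprime
    est <- out$estimator
  }
  expect_lt(abs(mean(resid[-(1:200)])), 3 * stats::sd(resid) / sqrt(3800))
})

test_that("policy-gradient update respects its trivial invariances", {
  set.seed(4)
  W <- matrix(rnorm(6), 2, 3)
  mask <- matrix(c(1, 1, 0, 1, 1, 1), 2, 3)
  W <- W * mask
  attr(W, "mask") <- mask
  ep <- list(list(fprime = 0.3, sigma = c(1L, 0L),
                  elig = matrix(rnorm(6), 2, 3)))
  expect_equal(prl_update(W, ep, 0), W)              # R' = 0
  W2 <- prl_update(W, ep, 0.5)
  expect_equal(W2[2, ], W[2, ])                      # silent neuron frozen
  expect_false(isTRUE(all.equal(W2[1, 1], W[1, 1])))
  expect_equal(W2[1, 2], 0)                          # masked synapse stays 0
  expect_error(prl_update(W, list(list(fprime = 1)), 1), "invalid episode")
  expect_error(prl_update(W, ep, c(1, 2)), "scalar")
})

test_that("average update climbs the exact expected reward", {
  k <- toy_kernels()
  e <- toy_escape()
  pat <- generate_frozen_pattern(3, rate = 250, duration = 10, seed = 5)
  psp <- popgrad:::psp_matrix(pat, k, e)
  pop <- population_config(n_neurons = 2, connect_prob = 1)
  set.seed(5)
  W <- matrix(rnorm(6, 0, 0.1), 2, 3)
  eta <- 0.3
  er <- numeric(121)
  er[1] <- exact_expected_reward(W, psp, k, e, pop)
  for (b in 1:120) {
    M <- W * 0
    for (ep in 1:150) {
      sigma <- integer(2); E <- matrix(0, 2, 3)
      for (i in 1:2) {
        s <- simulate_neuron(W[i, ], pat, k, e, psp = psp)
        sigma[i] <- s$train$fired
        E[i, ] <- eligibility_trace(psp, s$spike_steps, s$u, e)
      }
      A <- sum(sigma)
      D <- sample_decision(decision_prob(A, pop))
      M <- M + D * decision_feedback(D, A, pop) * (sigma * E)
    }
    W <- W + eta * M / 150
    er[b + 1] <- exact_expected_reward(W, psp, k, e, pop)
  }
  expect_gt(er[121] - er[1], 0.15)
  expect_lt(wilcox.test(diff(er), alternative = "greater")$p.value, 0.01)
})

test_that("binary neurons and the covariance rule behave as stated", {
  expect_equal(binary_forward(c(0, 0), c(1, 1))$sigma_mean, 0.5)
  expect_equal(binary_forward(c(50, 50), c(1, 1))$sigma_mean, 1,
               tolerance = 1e-12)
  set.seed(6)
  w <- c(0.4, -0.3); x <- c(1, 1)
  m <- binary_forward(w, x)$sigma_mean
  draws <- vapply(seq_len(1e4), function(i)
    binary_forward(w, x)$sigma, integer(1))
  expect_lt(abs(mean(draws) - m), 3 * sqrt(m * (1 - m) / 1e4))

  # no deviation, no change; no-subtraction variant frozen at sigma = 0
  cfg <- learn_config(nu = 0.2)
  pop <- population_config(n_neurons = 4)
  expect_equal(pcov_update(w, x, sigma = 1, sigma_center = 1, D = 1, A = 3,
                           rprime = 0.7, cfg, pop), w)
  expect_equal(pcov_update(w, x, sigma = 0, sigma_center = 0, D = 0, A = 1,
                           rprime = 0.7, cfg, pop), w)

  # covariance fixed point: reward independent of the response
  set.seed(7)
  n <- 5000
  deltas <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    fw <- binary_forward(w, x)
    A <- fw$sigma + rbinom(1, 3, 0.5)  # other neurons independent
    D <- sample_decision(decision_prob(A, pop))
    R <- sample(c(-1, 1), 1)           # independent of everything
    deltas[i, ] <- pcov_update(w, x, fw$sigma, fw$sigma_mean, D, A,
                               rprime = R, cfg, pop) - w
  }
  m_d <- colMeans(deltas)
  se_d <- apply(deltas, 2, stats::sd) / sqrt(n)
  expect_true(all(abs(m_d) < 3 * se_d))
})
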