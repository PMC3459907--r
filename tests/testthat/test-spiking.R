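test_that("frozen Poisson patterns are reproducible with the right mass", {
  p <- generate_frozen_pattern(100, rate = 6, duration = 500, seed = 1)
  total <- sum(lengths(p$spikes))
  expect_lt(abs(total - 300), 4 * sqrt(300))  # mean 100 * 6Hz * 0.5s
  expect_true(all(vapply(p$spikes, function(s)
    !length(s) || (all(s >= 0 & s < 500) && !is.unsorted(s, strictly = TRUE)),
    logical(1))))

  p2 <- generate_frozen_pattern(100, rate = 6, duration = 500, seed = 1)
  expect_identical(p$spikes, p2$spikes)
  p3 <- generate_frozen_pattern(100, rate = 6, duration = 500, seed = 2)
  expect_false(identical(p$spikes, p3$spikes))

  tiny <- generate_frozen_pattern(1, rate = 6, duration = 1e-4, seed = 7)
  expect_identical(lengths(tiny$spikes), 0L)
  expect_equal(tiny$duration, 1e-4)
  expect_equal(tiny$n_channels, 1L)

  expect_error(generate_frozen_pattern(3, rate = 0, duration = 10, seed = 1))
  expect_error(generate_frozen_pattern(3, rate = 6, duration = -1, seed = 1))
  expect_error(generate_frozen_pattern(0, rate = 6, duration = 10, seed = 1))
})

test_that("patterns round-trip through JSON", {
  p <- generate_frozen_pattern(5, rate = 20, duration = 50, seed = 4,
                               pattern_id = "hand14")
  f <- withr::local_tempfile(fileext = ".json")
  write_spike_pattern(p, f)
  q <- read_spike_pattern(f)
  expect_equal(q$pattern_id, "hand14")
  expect_equal(q$n_channels, 5L)
  expect_equal(q$spikes, p$spikes, tolerance = 1e-12)
})

test_that("PSP traces are causal and peak where the kernel peaks", {
  k <- toy_kernels()
  pat <- manual_pattern(list(numeric(0), 5), duration = 40)
  grid <- seq(0, 39.99, by = 0.01)
  expect_equal(psp_trace(pat, 1, k, grid), numeric(length(grid)))

  tr <- psp_trace(pat, 2, k, grid)
  expect_true(all(tr[grid <= 5] == 0))           # causal
  expect_lt(tr[which(grid > 5)[1]], 1e-2)        # rises from 0
  # analytic argmax of the double exponential:
  tau_star <- log(k$tau_m / k$tau_s) * k$tau_m * k$tau_s /
    (k$tau_m - k$tau_s)
  expect_equal(tau_star, 4.6210, tolerance = 1e-4)
  expect_equal(grid[which.max(tr)] - 5, tau_star, tolerance = 0.02)

  expect_error(psp_trace(pat, 3, k, grid))
})

test_that("membrane simulation matches constant-potential closed forms", {
  k <- toy_kernels()
  # resting potential far below threshold: essentially never fires
  k_low <- kernel_params(tau_m = 10, tau_s = 2.5,
                         u_rest = 0.5 - 20 * 0.3, eps_amp = 1,
                         kappa_amp = 0)
  e <- toy_escape()
  pat <- toy_pattern()
  sim <- simulate_neuron(rep(0, 3), pat, k_low, e, seed = 1)
  expect_identical(sim$train$fired, 0L)
  expect_equal(length(sim$train$spikes), 0L)

  # empty input, u_rest = theta: homogeneous Bernoulli(rho0 * dt) per step
  k_th <- kernel_params(tau_m = 10, tau_s = 2.5, u_rest = 0.5,
                        eps_amp = 1, kappa_amp = 0)
  empty <- manual_pattern(list(numeric(0)), duration = 50)
  psp <- popgrad:::psp_matrix(empty, k_th, e)
  set.seed(42)
  counts <- vapply(seq_len(1000), function(i) {
    length(simulate_neuron(0, empty, k_th, e, psp = psp)$train$spikes)
  }, numeric(1))
  expected <- 50 * e$rho0        # rho(theta) * T, with rho*dt = 0.05 each
  se <- sqrt(50 * e$rho0 * (1 - e$rho0)) / sqrt(1000)
  expect_lt(abs(mean(counts) - expected), 3 * se)

  expect_error(simulate_neuron(rep(0, 5), pat, toy_kernels(), e),
               "afferents")
})

test_that("each output spike resets the potential by kappa_amp", {
  k <- toy_kernels(kappa_amp = 0.7)
  e <- toy_escape()
  drive <- rep(0.4, 10)
  u <- popgrad:::clamped_potential(drive, 4L, k, e)
  expect_equal(u[1:4], drive[1:4])   # reset acts only after the spike
  expect_equal(drive[5] - u[5], 0.7 * exp(-e$dt / k$tau_m),
               tolerance = 1e-12)
  # as dt -> 0 the drop approaches kappa_amp
  e_fine <- toy_escape(dt = 1e-4)
  u_fine <- popgrad:::clamped_potential(rep(0.4, 10), 4L, k, e_fine)
  expect_equal(0.4 - u_fine[5], 0.7, tolerance = 1e-4)
})

test_that("spike-train likelihood normalizes and matches simulation", {
  k <- toy_kernels()
  # empty output at constant potential u = theta: pure survival term
  k_th <- kernel_params(tau_m = 10, tau_s = 2.5, u_rest = 0.5,
                        eps_amp = 1, kappa_amp = 0)
  e <- toy_escape()
  empty <- manual_pattern(list(numeric(0)), duration = 50)
  expect_equal(log_likelihood(0, empty, numeric(0), k_th, e),
               -e$rho0 * 50)

  # enumeration over all outputs on a 3-step grid
  pat <- manual_pattern(list(0.2), duration = 3)
  w <- 0.5
  outputs <- lapply(0:7, function(m) (which(bitwAnd(m, 2^(0:2)) > 0) - 1) * 1)
  tot_bern <- sum(vapply(outputs, function(o)
    exp(log_likelihood(w, pat, o, k, e, form = "bernoulli")), numeric(1)))
  expect_equal(tot_bern, 1, tolerance = 1e-12)
  # the product density normalizes in the small-rho*dt limit
  e_small <- toy_escape(rho0 = 1e-4)
  tot_dens <- sum(vapply(outputs, function(o)
    exp(log_likelihood(w, pat, o, k, e_small, form = "density")),
    numeric(1)))
  expect_equal(tot_dens, 1, tolerance = 1e-6)

  # exp(logL) matches the empirical frequency of a discretized output
  psp <- popgrad:::psp_matrix(pat, k, e)
  e_hot <- toy_escape(rho0 = 0.2, theta = 0.2)
  set.seed(99)
  sims <- vapply(seq_len(3e4), function(i) {
    s <- simulate_neuron(w, pat, k, e_hot, psp = psp)$spike_steps
    paste(s, collapse = ",")
  }, character(1))
  target <- 2L  # the output with a single spike at grid step 2
  p_hat <- mean(sims == "2")
  p_mod <- exp(log_likelihood(w, pat, (target - 1) * 1, k, e_hot,
                              form = "bernoulli"))
  se <- sqrt(p_mod * (1 - p_mod) / 3e4)
  expect_lt(abs(p_hat - p_mod), 4 * se)

  # raising a weight whose PSP is positive at the spike raises log P
  pat2 <- manual_pattern(list(1), duration = 12)
  out <- 5  # ~ at the PSP peak of the channel's spike at 1 ms
  ll0 <- log_likelihood(0.2, pat2, out, k, e)
  ll1 <- log_likelihood(0.4, pat2, out, k, e)
  expect_gt(ll1, ll0)

  expect_error(log_likelihood(w, pat, 5.0, k, e), "window")
})

test_that("escape rate is strictly increasing in the potential", {
  e <- toy_escape()
  u <- seq(-2, 2, by = 0.1)
  expect_true(all(diff(popgrad:::escape_rate(u, e)) > 0))
})
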