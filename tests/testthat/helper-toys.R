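# Small shared fixtures: a 3-afferent pattern on a short grid, with escape
# parameters putting rho*dt ~ 0.01 so the discrete Bernoulli law and the
# continuous product density agree closely.

toy_kernels <- function(kappa_amp = 0.5) {
  kernel_params(tau_m = 10, tau_s = 2.5, u_rest = 0, eps_amp = 1,
                kappa_amp = kappa_amp)
}

toy_escape <- function(rho0 = 0.05, theta = 0.5, delta_u = 0.3, dt = 1) {
  escape_params(rho0 = rho0, theta = theta, delta_u = delta_u, dt = dt)
}

toy_pattern <- function(n_channels = 3, duration = 20, rate = 100, seed = 3) {
  generate_frozen_pattern(n_channels, rate, duration, seed)
}

# A pattern with hand-placed spike times.
manual_pattern <- function(spikes, duration) {
  structure(list(n_channels = length(spikes), duration = duration,
                 spikes = lapply(spikes, as.numeric),
                 pattern_id = "manual"),
            class = "spike_pattern")
}

# Exact P(neuron fires >= 1 spike): on the silent trajectory no resets
# occur, so the no-spike probability is the product over the reset-free
# potential.
exact_fire_prob <- function(w, psp, kernels, escape) {
  u <- kernels$u_rest + as.vector(w %*% psp)
  p <- pmin(1, escape$rho0 * exp((u - escape$theta) / escape$delta_u) *
              escape$dt)
  1 - prod(1 - p)
}

# Exact expected reward E[D] of the two-neuron toy readout (independent
# neurons, decision sampled from the logistic readout of A).
exact_expected_reward <- function(W, psp, kernels, escape, pop) {
  q <- apply(W, 1, exact_fire_prob, psp = psp, kernels = kernels,
             escape = escape)
  pa <- c((1 - q[1]) * (1 - q[2]),
          q[1] * (1 - q[2]) + (1 - q[1]) * q[2],
          q[1] * q[2])
  sum(pa * vapply(0:2, decision_prob, numeric(1), cfg = pop))
}

# Paper-printed expected bank payoff table (gambler stop 11..18 by croupier
# stop 13..19), used as the analytic oracle target.
printed_payoff_table <- function() {
  matrix(c(
    0.2982, 0.3164, 0.3027, 0.2544, 0.1689, 0.0436, -0.1237,
    0.1635, 0.2015, 0.2076, 0.1791, 0.1130, 0.0066, -0.1427,
    0.1052, 0.1587, 0.1806, 0.1679, 0.1176, 0.0266, -0.1077,
    0.0438, 0.1134, 0.1536, 0.1597, 0.1282, 0.0560, -0.0598,
    0.0119, 0.0706, 0.1289, 0.1555, 0.1450, 0.0940, -0.0008,
    0.0143, 0.0607, 0.1085, 0.1557, 0.1685, 0.1411,  0.0702,
    0.0543, 0.0893, 0.1254, 0.1628, 0.1989, 0.1980,  0.1539,
    0.1349, 0.1598, 0.1854, 0.2120, 0.2394, 0.2651,  0.2509),
    nrow = 8, byrow = TRUE,
    dimnames = list(gambler = 11:18, croupier = 13:19))
}

# Printed final-hand distributions for stopping values 15 and 16
# (support 15..21 / 16..21 plus bust).
printed_stopping_rows <- function() {
  list(
    s15 = c(`15` = 0.1206, `16` = 0.1247, `17` = 0.1194, `18` = 0.1138,
            `19` = 0.1078, `20` = 0.1546, `21` = 0.0944, bust = 0.1648),
    s16 = c(`16` = 0.1247, `17` = 0.1287, `18` = 0.1231, `19` = 0.1170,
            `20` = 0.1638, `21` = 0.1036, bust = 0.2390))
}
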