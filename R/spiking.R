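#' Spike-response-model kernel parameters
#'
#' Bundles the parameters of the two response kernels of the neuron model:
#' the postsynaptic-potential (PSP) kernel
#' \deqn{\epsilon(\tau) = \epsilon_0 (e^{-\tau/\tau_m} - e^{-\tau/\tau_s})}
#' and the after-spike reset kernel
#' \deqn{\kappa(\tau) = -\kappa_0 e^{-\tau/\tau_m},}
#' both vanishing for \eqn{\tau \le 0}. Potentials are in arbitrary units,
#' times in milliseconds.
#'
#' @param tau_m Membrane time constant (ms).
#' @param tau_s Synaptic time constant (ms); must differ from `tau_m`.
#' @param u_rest Resting potential (a.u.).
#' @param eps_amp PSP kernel amplitude \eqn{\epsilon_0 > 0} (a.u.).
#' @param kappa_amp Reset amplitude \eqn{\kappa_0 \ge 0} (a.u., applied
#'   negatively after each output spike).
#' @return An object of class `kernel_params`.
#' @export
#' @examples
#' kernel_params()
kernel_params <- function(tau_m = 10, tau_s = 2.5, u_rest = 0,
                          eps_amp = 1, kappa_amp = 1) {
  if (tau_m <= 0 || tau_s <= 0) stop_invalid("time constants must be positive")
  if (tau_s == tau_m) stop_invalid("tau_s must differ from tau_m")
  if (eps_amp <= 0) stop_invalid("eps_amp must be positive")
  if (kappa_amp < 0) stop_invalid("kappa_amp must be non-negative")
  structure(list(tau_m = tau_m, tau_s = tau_s, u_rest = u_rest,
                 eps_amp = eps_amp, kappa_amp = kappa_amp),
            class = "kernel_params")
}

#' Escape-noise parameters
#'
#' The neuron fires stochastically with instantaneous rate
#' \deqn{\rho(u) = \rho_0 \exp((u - \theta)/\Delta u),}
#' i.e. within one simulation step of width `dt` it emits a spike with
#' probability \eqn{\min(1, \rho(u)\,dt)}. The exponential escape function is
#' the one for which \eqn{\rho'/\rho} is constant, which keeps the
#' log-likelihood gradient of a spike train in the simple form used by
#' [eligibility_trace()].
#'
#' @param rho0 Base firing rate at threshold (1/ms).
#' @param theta Threshold potential (a.u.).
#' @param delta_u Escape-noise width (a.u.); smaller values make firing more
#'   deterministic.
#' @param dt Simulation time step (ms).
#' @return An object of class `escape_params`.
#' @export
escape_params <- function(rho0 = 0.01, theta = 1, delta_u = 0.2, dt = 1) {
  if (rho0 <= 0) stop_invalid("rho0 must be positive")
  if (delta_u <= 0) stop_invalid("delta_u must be positive")
  if (dt <= 0) stop_invalid("dt must be positive")
  structure(list(rho0 = rho0, theta = theta, delta_u = delta_u, dt = dt),
            class = "escape_params")
}

escape_rate <- function(u, escape) {
  escape$rho0 * exp((u - escape$theta) / escape$delta_u)
}

#' Generate a frozen Poisson spike pattern
#'
#' Draws one homogeneous Poisson spike train per afferent channel. The
#' pattern is "frozen": it is generated once and then presented repeatedly
#' with identical spike timings, so the same `(arguments, seed)` pair always
#' reproduces byte-identical spike times.
#'
#' @param n_channels Number of afferent channels.
#' @param rate Poisson rate per channel in Hz.
#' @param duration Pattern duration in ms.
#' @param seed Integer seed; identical seeds give identical patterns.
#' @param pattern_id Optional key naming the game state this pattern encodes.
#' @return An object of class `spike_pattern` with fields `n_channels`,
#'   `duration`, `spikes` (list of sorted spike-time vectors in ms) and
#'   `pattern_id`.
#' @export
#' @examples
#' p <- generate_frozen_pattern(10, rate = 6, duration = 500, seed = 1)
#' lengths(p$spikes)
generate_frozen_pattern <- function(n_channels, rate, duration, seed,
                                    pattern_id = NA_character_) {
  if (n_channels < 1) stop_invalid("n_channels must be >= 1")
  if (rate <= 0) stop_invalid("rate must be positive")
  if (duration <= 0) stop_invalid("duration must be positive")
  rate_ms <- rate / 1000  # Hz -> spikes per ms
  spikes <- with_seed(seed, {
    counts <- stats::rpois(n_channels, lambda = rate_ms * duration)
    lapply(seq_len(n_channels), function(j) {
      sort(runif(counts[j], min = 0, max = duration))
    })
  })
  structure(list(n_channels = as.integer(n_channels), duration = duration,
                 spikes = spikes, pattern_id = pattern_id),
            class = "spike_pattern")
}

#' @export
print.spike_pattern <- function(x, ...) {
  cat(sprintf("Frozen spike pattern '%s': %d channels, %.6g ms, %d spikes\n",
              x$pattern_id, x$n_channels, x$duration,
              sum(lengths(x$spikes))))
  invisible(x)
}

#' Read and write frozen spike patterns as JSON
#'
#' Serializes a pattern as `{pattern_id, n_channels, duration_ms, spikes}`
#' with times in ms.
#'
#' @param pattern A [generate_frozen_pattern()] object.
#' @param path File path.
#' @return `write_spike_pattern()` returns `path` invisibly;
#'   `read_spike_pattern()` returns the `spike_pattern`.
#' @export
write_spike_pattern <- function(pattern, path) {
  jsonlite::write_json(
    list(pattern_id = pattern$pattern_id, n_channels = pattern$n_channels,
         duration_ms = pattern$duration, spikes = pattern$spikes),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_spike_pattern
#' @export
read_spike_pattern <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  spikes <- lapply(x$spikes, as.numeric)
  structure(list(n_channels = as.integer(x$n_channels),
                 duration = as.numeric(x$duration_ms), spikes = spikes,
                 pattern_id = x$pattern_id),
            class = "spike_pattern")
}

#' An output spike train
#'
#' @param spikes Sorted spike times in ms.
#' @return An object of class `spike_train` with fields `spikes` and `fired`
#'   (1 if at least one spike, else 0), the spike/no-spike code read out by
#'   the population decision unit.
#' @export
spike_train <- function(spikes = numeric(0)) {
  spikes <- sort(as.numeric(spikes))
  structure(list(spikes = spikes, fired = as.integer(length(spikes) > 0)),
            class = "spike_train")
}

# PSP kernel on a vector of lags (ms); zero for tau <= 0.
eps_kernel <- function(tau, kernels) {
  ifelse(tau > 0,
         kernels$eps_amp * (exp(-tau / kernels$tau_m) -
                            exp(-tau / kernels$tau_s)),
         0)
}

#' Postsynaptic-potential trace of one input channel
#'
#' Sums the PSP kernel over all spikes of the channel:
#' \eqn{\mathrm{PSP}_j(t) = \sum_{t^s \le t} \epsilon(t - t^s)}. Causal: the
#' trace is zero before the first input spike.
#'
#' @param pattern A [generate_frozen_pattern()] object.
#' @param channel Channel index (1-based).
#' @param kernels A [kernel_params()] object.
#' @param grid Vector of evaluation times in ms.
#' @return Numeric vector of PSP values on `grid`.
#' @export
psp_trace <- function(pattern, channel, kernels, grid) {
  if (channel < 1 || channel > pattern$n_channels)
    stop_invalid("invalid channel index")
  ts <- pattern$spikes[[channel]]
  if (!length(ts)) return(numeric(length(grid)))
  rowSums(eps_kernel(outer(grid, ts, "-"), kernels))
}

# PSP traces for all channels on the dt grid: n_channels x n_steps matrix.
# Computed once per frozen pattern and reused across trials.
psp_matrix <- function(pattern, kernels, escape) {
  grid <- sim_grid(pattern, escape)
  t(vapply(seq_len(pattern$n_channels),
           function(j) psp_trace(pattern, j, kernels, grid),
           numeric(length(grid))))
}

# Grid times: 0, dt, ..., duration - dt (left edges of the dt bins).
sim_grid <- function(pattern, escape) {
  n_steps <- max(1L, round(pattern$duration / escape$dt))
  (seq_len(n_steps) - 1) * escape$dt
}

#' Simulate one spike-response neuron with escape noise
#'
#' Computes the membrane potential
#' \deqn{u(t) = u_{rest} + \sum_j w_j \mathrm{PSP}_j(t) +
#'   \sum_{t^f < t} \kappa(t - t^f)}
#' on the discrete `dt` grid and emits a spike at each step with probability
#' \eqn{\min(1, \rho(u)\,dt)}. Output spikes live on the grid (no
#' within-step interpolation).
#'
#' @param weights_row Numeric vector of synaptic strengths, one per afferent.
#' @param pattern Input [generate_frozen_pattern()] object.
#' @param kernels,escape Model parameters.
#' @param seed Optional integer seed for the firing noise.
#' @param psp Optional precomputed PSP matrix from the same pattern/kernels
#'   (rows = channels, columns = grid steps), to avoid recomputing it for a
#'   frozen pattern presented repeatedly.
#' @return A list of class `srm_sim` with the output `train`
#'   ([spike_train()]), `spike_steps` (1-based grid indices), membrane trace
#'   `u`, per-step firing probability `p`, the `grid` times and the `psp`
#'   matrix used -- everything the learning rule needs.
#' @export
simulate_neuron <- function(weights_row, pattern, kernels, escape,
                            seed = NULL, psp = NULL) {
  if (is.null(psp)) psp <- psp_matrix(pattern, kernels, escape)
  if (length(weights_row) != nrow(psp))
    stop_invalid("weights_row length must equal the number of afferents")
  grid <- sim_grid(pattern, escape)
  drive <- kernels$u_rest + as.vector(weights_row %*% psp)
  unif <- with_seed(seed, runif(length(grid)))
  sim <- srm_simulate_cpp(drive, escape$rho0, escape$theta, escape$delta_u,
                          escape$dt, kernels$kappa_amp, kernels$tau_m, unif)
  steps <- as.integer(sim$spike_steps)
  structure(list(train = spike_train(grid[steps]), spike_steps = steps,
                 u = sim$u, p = sim$p, grid = grid, psp = psp),
            class = "srm_sim")
}

# Membrane trace with the output spike train clamped: resets are taken from
# the given output, not sampled.
clamped_potential <- function(drive, spike_steps, kernels, escape) {
  u <- drive
  n <- length(drive)
  for (f in spike_steps) {
    if (f < n) {
      idx <- (f + 1L):n
      u[idx] <- u[idx] - kernels$kappa_amp *
        exp(-((idx - f) * escape$dt) / kernels$tau_m)
    }
  }
  u
}

output_steps <- function(output, pattern, escape) {
  times <- if (inherits(output, "spike_train")) output$spikes
           else sort(as.numeric(output))
  if (any(times < 0 | times >= pattern$duration))
    stop_invalid("output spike outside the pattern window")
  steps <- round(times / escape$dt) + 1L
  n_steps <- max(1L, round(pattern$duration / escape$dt))
  if (any(steps > n_steps)) stop_invalid("output spike outside the grid")
  steps
}

#' Log-likelihood of an output spike train
#'
#' Probability (log scale) that the neuron produces exactly the given output
#' spike train in response to the input pattern, with the membrane potential
#' computed including the resets caused by that output (clamped likelihood).
#'
#' Two equivalent-to-first-order forms are available. `"density"` is the
#' point-process product density
#' \eqn{\log P = \sum_f \log(\rho(u(t^f))\,dt) - \sum_t \rho(u(t))\,dt,}
#' whose weight gradient is exactly the eligibility trace of
#' [eligibility_trace()]. `"bernoulli"` is the exact discrete law of the
#' simulator, \eqn{\sum_f \log p_t + \sum_{\neg f} \log(1 - p_t)} with
#' \eqn{p_t = \min(1, \rho\,dt)}; summed over all possible discretized
#' outputs it is exactly normalized. The two agree to \eqn{O(\rho\,dt)}.
#'
#' @param weights_row,pattern,kernels,escape As in [simulate_neuron()].
#' @param output A [spike_train()] or numeric vector of output spike times
#'   (ms) inside the pattern window.
#' @param form `"density"` (default) or `"bernoulli"`; see Details.
#' @param psp Optional precomputed PSP matrix.
#' @return The log-likelihood (finite for finite inputs).
#' @export
log_likelihood <- function(weights_row, pattern, output, kernels, escape,
                           form = c("density", "bernoulli"), psp = NULL) {
  form <- match.arg(form)
  if (is.null(psp)) psp <- psp_matrix(pattern, kernels, escape)
  if (length(weights_row) != nrow(psp))
    stop_invalid("weights_row length must equal the number of afferents")
  steps <- output_steps(output, pattern, escape)
  drive <- kernels$u_rest + as.vector(weights_row %*% psp)
  u <- clamped_potential(drive, steps, kernels, escape)
  rho <- escape_rate(u, escape)
  if (form == "density") {
    sum(log(rho[steps] * escape$dt)) - sum(rho * escape$dt)
  } else {
    p <- pmin(1, rho * escape$dt)
    fire <- logical(length(p)); fire[steps] <- TRUE
    sum(log(p[fire])) + sum(log1p(-p[!fire]))
  }
}
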