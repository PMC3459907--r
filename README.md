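# popgrad

Spike-based population reinforcement learning of Nash equilibria in
two-player games.

## What this package is for

How can a nervous system learn optimal behavior when the environment
contains another adaptive agent? `popgrad` is for computational
neuroscientists and neuroeconomists studying that question. It implements
a population of stochastically spiking neurons whose synapses follow a
reward-modulated policy-gradient rule (population reinforcement learning),
the comparison learners standard in the field — covariance learning with
binary neurons, SARSA temporal-difference learning with a softmax policy,
and the Roth–Erev propensity models — and two classical game environments
in which their equilibrium behavior can be judged exactly:

* a simplified **blackjack** against the bank, whose optimal strategy pair
  is a *pure* Nash equilibrium (a saddle point of the expected payoff
  matrix), and
* the **inspector game** (work/shirk versus inspect/pass), whose unique
  equilibrium is *mixed*: the employee shirks with probability equal to
  the inspection cost `i`, the employer inspects with probability 1/2.

Both games come with exact analytic solvers (stopping-value distributions,
expected payoff matrix, saddle point, 2×2 mixed-equilibrium indifference
solver), so every simulation in the package is validated against a closed
form rather than another simulation.

## The model in brief

Each game state is a frozen spatio-temporal Poisson spike pattern. A
population of `N` spike-response neurons with escape noise
(`rho(u) = rho0 * exp((u - theta)/delta_u)`) integrates it; the binary
behavioral decision `D` is sampled from a logistic readout of the
population activity `A` (the number of neurons that spiked). After each
episode with reward `R`, every synapse moves by the product of four
factors:

```
dw_ij = eta * (R - Rbar_s)            # reward prediction error
        * (D - P(D=1|A)) / (lambda*sqrt(N))   # decision feedback f'
        * sigma_i                     # the neuron's own decision
        * e_ij                        # eligibility trace
```

where the eligibility trace `e_ij` is the gradient of the log-likelihood
of the neuron's emitted spike train — per afferent, the summed PSP at the
output spike times minus the rate-weighted PSP integral, divided by
`delta_u`. The rule performs stochastic gradient ascent on the expected
reward; the test suite verifies the gradient identities numerically
(finite differences, zero-mean eligibility and feedback, cosine similarity
of the average update with the exact reward gradient above 0.9).

## Worked example

```r
library(popgrad)

m <- mean_payoff_matrix()          # expected bank payoff, exact
find_saddle_point(m)$pairs
#>   row col row_label col_label     value
#> 1   5   4        15        16 0.1555441
```

The unique saddle point says: the gambler should stop drawing at hand
value 15 or more, the croupier at 16 or more, and the bank then gains
0.1555 per game on average (the asymmetric standoff rule is why the bank
profits at equilibrium). Simulating the game reproduces it:

```r
res <- run_match("blackjack", player_a = 15, player_b = 16,
                 n_trials = 2e4, master_seed = 3)
res$summary$mean_bank_reward
#> [1] 0.1528        # within Monte-Carlo error of 0.1555
```

For the inspector game, the generic indifference solver gives the mixed
equilibrium for any inspection cost:

```r
unlist(inspector_mixed_nash(inspector_config(0.2))[1:4])
#>    p_shirk  p_inspect v_employee v_employer
#>        0.2        0.5        0.5        1.6
```

Two spiking populations playing the inspector game against each other
drift toward exactly that mixture:

```r
res <- run_match("inspector",
  player_a = list(type = "prl", n_channels = 50, duration = 200,
                  pop = population_config(n_neurons = 10)),
  player_b = list(type = "prl", n_channels = 50, duration = 200,
                  pop = population_config(n_neurons = 10)),
  n_trials = 8000, cost_i = 0.3, master_seed = 1)
mean(res$trajectory$action_a[4001:8000])   # shirk rate, Nash value 0.3
#> [1] 0.30825
```

A thin command-line front end is installed with the package
(`exec/popgrad`): `popgrad solve-blackjack`, `popgrad stopping-dist 15`,
`popgrad nash --cost 0.2`, and `popgrad play --config cfg.yaml`.

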