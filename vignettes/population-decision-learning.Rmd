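---
title: "Population decision learning in two-player games: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population decision learning in two-player games: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popgrad)
```

## The scientific problem

In repeated two-player games the payoff of an action depends on the
opponent, and the opponent adapts. The optimal behavior is characterized by
a Nash equilibrium, which may be *pure* (a deterministic action per state,
as in the simplified blackjack implemented here) or *mixed* (actions taken
with fixed probabilities, as in the inspector game). `popgrad` implements a
biologically interpretable learner — a population of stochastically spiking
neurons whose synapses follow a reward-modulated policy-gradient rule — and
the standard comparison learners of the neuroeconomics literature
(covariance learning, SARSA with softmax, and the Roth–Erev propensity
models), together with the exact analytic solvers for both games that all
simulations are validated against.

## The neuron and population model

Each game state is encoded by a *frozen* spatio-temporal spike pattern:
afferent Poisson spike trains (6 Hz by default) drawn once and re-presented
with identical timings on every visit of that state. A population neuron is
a spike-response model: its membrane potential is the resting potential
plus a weighted sum of postsynaptic-potential (PSP) kernels
$\epsilon(\tau) \propto e^{-\tau/\tau_m} - e^{-\tau/\tau_s}$ over input
spikes, plus a reset kernel $-\kappa_0 e^{-\tau/\tau_m}$ after each of its
own spikes. Firing is stochastic with escape rate
$\rho(u) = \rho_0 e^{(u-\theta)/\Delta u}$; on the simulation grid the
neuron fires in a step of width $dt$ with probability $\min(1,\rho\,dt)$.
The exponential escape function is deliberate: it is the choice for which
$\rho'/\rho$ is constant, so the log-likelihood gradient of an output
spike train takes the simple two-term form used below.

The population decision is read out from the spike/no-spike code
$\sigma_i \in \{0,1\}$, $A = \sum_i \sigma_i$, and the binary behavioral
decision is sampled from the logistic
$P(D{=}1\mid A) = g\!\left((A - N/2)/(\lambda\sqrt N)\right)$.
Centering at $N/2$ and scaling by $\sqrt N$ keeps the argument of the same
order as the binomial fluctuations of $A$; the slope $\lambda$
(`readout_scale`) controls decision stochasticity. With zero-mean initial
weights $A$ is binomial around $N/2$, so this normalization also pins the
*initial* choice behavior at the random 50/50 prior the model assumes
before learning.

## The learning rule

After each episode with terminal reward $R$ every synapse moves by the
product of four factors:

$$\Delta w_{ij} \;=\; \underbrace{\eta\,(R - \bar R_s)}_{R'}\;
\underbrace{\frac{D - P(D{=}1\mid A)}{\lambda\sqrt N}}_{f'}\;
\sigma_i\; e_{ij},$$

where $\bar R_s$ is a running mean of the reward for stimulus $s$
(so the reward factor averages to zero for each stimulus individually),
$f' = \partial \log P(D\mid A)/\partial A$ is the global decision-feedback
signal broadcast to all synapses, $\sigma_i$ is the neuron's own decision,
and the eligibility trace

$$e_{ij} = \frac{1}{\Delta u}\Big[\sum_{t^f} \mathrm{PSP}_j(t^f)
 - \sum_t \rho(u(t))\,\mathrm{PSP}_j(t)\,dt\Big]$$

is exactly $\partial \log P(y_i)/\partial w_{ij}$, the spike-train
log-likelihood gradient. Its positive spike-timing term and negative
potential term balance, so the eligibility is zero on average; the test
suite verifies both the gradient identity (finite differences, relative
error below $10^{-4}$) and the zero mean, and checks on a two-neuron toy
system that the Monte-Carlo average update direction has cosine similarity
above 0.9 with the finite-difference gradient of the exact expected reward.
At $N = 1$ the rule reduces to the single-neuron policy-gradient rule for
escape-rate neurons.

For blackjack, where one game involves several decisions, the per-decision
terms $f'_d\,\sigma_{i,d}\,e_{ij,d}$ are summed over the episode (the
standard episodic policy-gradient form). Because $\bar R$ is kept per
stimulus, each decision period carries its own $R'_d = \eta(R - \bar
R_{s_d})$; for single-state games this reduces exactly to one scalar $R'$.

## Two likelihood forms, one gradient

The simulator is a discrete Bernoulli approximation of the escape-noise
point process. `log_likelihood()` therefore offers two forms:

* `"density"` (default): the product density
  $\sum_f \log(\rho(u(t^f))\,dt) - \sum_t \rho\,dt$. Its weight gradient is
  *exactly* the eligibility trace, which keeps the learning rule and the
  likelihood an exact dual pair.
* `"bernoulli"`: the exact discrete law of the simulator,
  $\sum_f \log p_t + \sum_{\neg f}\log(1-p_t)$ with
  $p_t = \min(1, \rho\,dt)$. Summed over every possible discretized output
  it is exactly normalized, which is what the enumeration tests assert.

The two agree to $O(\rho\,dt)$; all toy fixtures keep $\rho\,dt \lesssim
0.05$ so both views are consistent to well within the test tolerances.

## The games and their exact solvers

**Blackjack.** Infinite-deck approximation: the card value distribution is
constant (value 10 with mass 4/13; 2–9 and ace-as-11 with mass 1/13 each).
A strategy is a stopping value: draw while the hand is below it. The final
hand-value distribution is computed by exact forward iteration — mass below
the stopping value is repeatedly convolved with the card distribution —
and the expected bank payoff for a strategy pair is the expectation of the
asymmetric payoff (gambler bust loses immediately; standoffs go to the
bank) under the product distribution. The resulting 8×7 matrix over the
modeled ranges (gambler 11–18, croupier 13–19) has a unique saddle point at
(15, 16): the pure Nash equilibrium, with bank payoff 0.1555. Hands are
modeled as cumulative sums of i.i.d. draws from zero: the initial two-card
hand is simply the first two forced draws, and below the modeled range the
draw is always safe (maximum card 11), so learners are only consulted
inside the modeled range; above it the stop is forced. A 32-card
(piquet-style) deck used in human experiments is available as an
alternative card distribution but has no analytic benchmark and is
untested against one.

**Inspector game.** A 2×2 bimatrix game (work/shirk versus inspect/pass)
with inspection cost $i \in (0,1)$. The package solves the two
indifference equations generically; the unique interior equilibrium has
$P(\text{shirk}) = i$, $P(\text{inspect}) = 1/2$, employee value $0.5$ for
every $i$ and employer value $2 - 2i$. The solver flags degenerate payoff
tables instead of returning a spurious mixture.

```{r}
m <- mean_payoff_matrix()
find_saddle_point(m)$pairs
unlist(inspector_mixed_nash(inspector_config(0.3))[1:4])
```

## Parameters that matter

| parameter | default | role |
|---|---|---|
| `tau_m`, `tau_s` | 10 ms, 2.5 ms | PSP kernel shape (peak at ~4.6 ms) |
| `rho0`, `theta`, `delta_u` | 0.01/ms, 1, 0.2 | escape rate; `delta_u` also scales the eligibility |
| `dt`, pattern duration | 1 ms, 500 ms | simulation grid; spikes live on the grid |
| `n_channels`, pattern rate | 100, 6 Hz | stimulus encoding dimensionality |
| `n_neurons`, `connect_prob` | 50, 0.5 | population size and afferent sharing |
| `readout_scale` | 1 | decision stochasticity; bounds reachable choice probabilities |
| `eta`, `gamma_rbar` | 0.05, 0.05 | reward scaling and running-mean rate |
| `nu` | 0.05 | covariance-rule learning rate |
| `alpha`, `beta` | 0.1, 3 | SARSA learning rate and softmax temperature |

Potentials are in arbitrary units; only differences relative to `delta_u`
matter. `learner_prl()` sets its default resting potential to
$\theta + \Delta u \log(\log 2/(\rho_0 T))$ so that a neuron with zero-mean
initial weights fires at least one spike with probability about one half —
the operating point at which the initial population decision is unbiased.
Initial weights are Gaussian with mean zero (sd 0.1) on a Bernoulli(0.5)
connectivity mask; masked-out synapses are exactly zero and never updated.

## Design choices where the design was open

* **Decision-sigmoid normalization.** Centering at $N/2$ with scale
  $\lambda\sqrt N$ (configurable) — the choice that matches binomial
  activity fluctuations and an unbiased initial decision.
* **Neuronal decision factor.** $\sigma_i$ enters the update as a raw
  $\{0,1\}$ indicator by default; robustness variants (mean-subtracted
  response, doubled or dropped negative eligibility term) are exposed as
  configuration switches rather than fixed, since the qualitative behavior
  is insensitive to them.
* **SARSA discounting.** None (episodic, both games are short finite
  episodes); intermediate blackjack draws earn reward 0.
* **RE3 two-action form.** Chosen propensity gains $r(1-\varepsilon)$, the
  other $r\varepsilon$, both decayed by $(1-\phi)$; with
  $\varepsilon = \phi = 0$ it reduces to RE1.
* **Running-rate analytics.** Decision sequences are low-pass filtered
  with rate 0.02 from the 0.5 random-choice prior; rate changes are
  computed by bin means, first differences, and a second exponential
  filter.

## What the simulations show (and at what scale)

The test suite runs scaled-down but otherwise unmodified experiments,
sized to finish in minutes on one CPU:

* *Fixed-strategy blackjack*: $10^5$ episodes at the Nash pair reproduce
  the analytic bank payoff within Monte-Carlo error; smaller runs check
  off-equilibrium pairs.
* *Two spiking populations in the inspector game* (10 neurons per
  population, 50 afferents, 200 ms patterns, $i = 0.3$, 8000 trials): the
  block-averaged shirk rate over the final half approaches the equilibrium
  value $i$, and the employer's rate of change correlates positively with
  the employee's deviation from equilibrium — the counteractive
  co-adaptation that makes the mixed equilibrium an oscillation center
  rather than a fixed point. The inspection rate converges on a much
  slower timescale and is not asserted at this run length.
* *Softmax impossibility*: at the mixed equilibrium both action values of
  a player are equal, so a softmax policy returns probability 1/2 at every
  inverse temperature and cannot represent the skewed equilibrium mixture
  $(i, 1-i)$ with $i \ne 1/2$. This is why value-based TD learning cannot
  settle on the mixed Nash equilibrium here.
* *Covariance learning*: with a population readout, individual binary
  neurons saturate in opposite directions and runs freeze at non-Nash
  *mixed* strategy pairs — the readout noise bounds reachable choice
  probabilities away from 0 and 1 for moderate $N$ (for $N = 10$,
  $\lambda = 1$ the reachable range is about $[0.17, 0.83]$). In the
  single-neuron variant, where the response effectively *is* the decision
  (steep readout), runs are absorbed into fully deterministic non-Nash
  strategy pairs. Both failure modes illustrate that covariance rules need
  not find the mixed equilibrium; the deterministic-absorption test uses
  the single-neuron configuration because that is where "deterministic"
  is attainable at all.

## What the synthetic stimuli do and do not emulate

Frozen Poisson patterns capture the *identity* coding of game states —
arbitrary, initially orderless stimuli whose meaning must be learned by
trial and error — but not stimulus similarity structure, neural noise
correlations, or any ordering prior over hand values. Tests passing on
these stimuli show that the learning rule extracts reward structure from
arbitrary spatio-temporal codes; they do not show how humans generalize
across neighboring hand values, and no claim about fitting human
behavioral data is made (that would require the behavioral datasets and
the fitted learning-rate values, neither of which ships with the package).

## Numerical notes and limitations

* The stopping-value recursion uses plain double convolutions; the
  accumulated error over the at most $\lceil s/2\rceil + 1$ draws is below
  $10^{-12}$, and all probability vectors are checked to sum to 1 at that
  tolerance.
* Saddle-point detection uses a $10^{-12}$ tie tolerance and returns all
  saddle points; ties and the no-saddle case are explicit results, not
  errors.
* Spike times live on the `dt` grid; there is no within-step
  interpolation, and the likelihood/simulator pair is kept consistent by
  construction (see the two forms above).
* Event-driven exact simulation, conductance-based neurons, online
  (low-pass, non-episodic) eligibility traces, reward-modulated STDP, and
  the neural implementation of the decision readout are out of scope.
* The learner-facing croupier/employer can be another learner or a fixed
  (possibly mixing) strategy. Against an employer fixed at the equilibrium
  inspection rate 1/2 the employee is exactly indifferent — its reward
  gradient vanishes everywhere — so no convergence of the shirk rate is
  expected or asserted in that configuration; the attracting time-average
  arises from two co-adapting learners.
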