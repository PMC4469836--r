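---
title: "A dopamine-serotonin basal ganglia model of utility-based decision making"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A dopamine-serotonin basal ganglia model of utility-based decision making}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bgutility)
```

## The model

`bgutility` simulates decision making in the basal ganglia as utility
maximization shaped by two neuromodulators.  Dopamine carries prediction
errors; serotonin sets how strongly outcome *risk* (variance) weighs
against outcome *value*.

The abstract core is a risk-sensitive reinforcement learner.  A value
table $Q(s,a)$ is trained by the temporal-difference rule
$Q \leftarrow Q + \eta_Q\,\delta$ with $\delta = r - Q$ for the
single-step tasks simulated here.  A risk table $h(s,a)$ is trained by a
second prediction error $\xi = \delta^2 - h$, whose fixed point is the
variance of $\delta$.  Decisions value each action by the utility

$$U = Q - \alpha\,\mathrm{sign}(Q)\,h,$$

which subtracts risk for gains ($Q>0$, risk aversion) and adds it for
losses ($Q<0$, risk seeking); we define $\mathrm{sign}(0)=0$ so the
utility degenerates to the value at exactly neutral $Q$.  The abstract
agent selects actions by softmax with inverse temperature $\beta$.

The network model grounds these quantities in three striatal medium
spiny neuron (MSN) pools.  D1R-expressing MSNs read out the value
($Q = y_{D1}$), D1R-D2R co-expressing MSNs the risk ($h = y_{D1D2}$),
and D2R MSNs drive the indirect pathway.  Cortico-striatal weights are
trained by a Hebbian rule gated by sigmoidal dopamine gain functions,
$\Delta w_P = \eta_P\,\lambda^{Str}_P(\delta)$: the D1 gain is an
increasing bipolar sigmoid of $\delta$, the D2 gain a decreasing one,
and the co-expressing pool responds with the *sum* of a D1-like and a
D2-like unipolar component, which yields a "U"-shaped gain that grows
with $|\delta|$ — the cellular mechanism for variance tracking
(`risk_tracking_demo()` reproduces this: the co-expressing read-out
follows $p(1-p)$ across Bernoulli reward probabilities).

Action selection happens downstream.  The direct pathway carries
$x^{DP}_i = \alpha_{D1}\lambda^{GPi}_{D1}(\delta_U)\,y_{D1}$ per action
channel, the indirect pathway
$x^{IP}_i = \alpha_{D2}\lambda^{GPi}_{D2}(\delta_U)\,y_{D2} +
\alpha_{D1D2}\,\mathrm{sign}(y_{D1})\,\lambda^{GPi}_{D1D2}(\delta_U)\,
y_{D1D2}$, where $\delta_U$ is the trial-to-trial *utility gradient* — a
second dopamine signal that switches between "Go" (exploit) and
"NoGo"/"Explore" modes.  The subthalamic nucleus (STN) and external
pallidum (GPe) form a coupled excitatory-inhibitory loop, one neuron per
available action, whose chaotic transients supply the exploration that
the abstract model gets from softmax noise.  GPi combines both pathways,
the thalamus integrates its (negated) output for 25 Euler steps, and the
channel with the largest thalamic activation is executed.  The three
serotonin multipliers $\alpha_{D1}, \alpha_{D2}, \alpha_{D1D2}$ scale
the three striatal drives; tryptophan depletion and Parkinson's disease
are modelled as lowered $\alpha$'s, and the disease's dopamine deficit
as a hard clamp $\delta \le \delta_{Lim}$ with a medication increment
$\delta_{Med}$ in the ON state (`apply_pd()`).

## Parameters that matter

* **Gain constants** $(c_1, c_2, c_3)$ per pool and site: shipped as the
  presets `table1` (variance-tracking demonstration), `table3` (GPi
  gating, all experiments), `table5`/`table6`/`table8` (striatal
  plasticity for the risk, reversal and PD experiments).  $c_1$ sets the
  response ceiling, the sign of $c_2$ the receptor direction, $-c_3$ the
  sigmoid midpoint.  All are unitless functions of a prediction error.
* **Learning rates** $\eta_{D1}, \eta_{D2}, \eta_{D1D2}$: per
  experiment, as published (risk: 0.3/0.1/0.1; reversal: 0.01 each; PD:
  0.01/0.1/0.1).
* **Serotonin multipliers**: risk task baseline
  $[1, 1, 1.32]$ vs depleted $[1, 1, 0.0012]$; reversal balanced
  $[1, 5, 1]$ vs depleted $[1, 2.25, 1]$; PD controls $[1, 1, 0.2]$,
  PD-OFF $[1, 0.99, 0.001]$ with $\delta_{Lim}=0.001$, PD-ON
  $[1, 0.2, 0.001]$ with $\delta_{Med}=0.021$.
* **Network constants**: $\epsilon_g = -\epsilon_s = -0.1$,
  $1/\tau_s = 0.1$, $1/\tau_g = 0.033$, STN slope 3, STN-to-GPi weight 1,
  25 integration steps.
* **Reward base** $r^b = 159.83$ ms for the risk task: juice amounts
  below it act as subjective losses, above it as gains.

## Conventions where the formulation is open

Several pieces of the published formulation do not pin down an
executable rule; the package fixes each one explicitly and exposes the
alternatives.

**The utility gradient $\delta_U$.**  The defining difference
$U_t(s_t,a_t) - U_{t-1}(s_t,a_{t-1})$ references the current action
before it has been selected.  The package default (`du_scope = "state"`)
compares the greedy utility of the current state under current weights
with the stored utility of the action executed at that state's previous
visit (stored at its selection time); this realizes the described
hill-climbing reading and keeps the comparison within a state, as the
defining expression does.  Three alternatives are available on every
agent and harness: `"action"` (the temporal gradient of the executed
action's utility — rises after rewards, falls after punishments),
`"trial"` (that same gradient broadcast globally to the next trial,
closest to a tonic dopamine broadcast) and `"global"` (greedy utility
against the previous trial across states, which adds between-state
utility jumps).  We compared all four on the three experiments before
fixing the default; the choice changes quantitative outcomes
substantially, and we document it rather than hide it.

**Selection read-out.**  "Maximum on integration" is read as the argmax
of the thalamic state after the final Euler step (with unit step the
thalamic state equals its afferent); `selection_rule = "integral"`
switches to the running time-integral.

**Initial conditions.**  STN and GPe states start each decision i.i.d.
uniform in $[-0.1, 0.1]$ from the agent's seeded stream; the source
model gives no initialization, and a small random kick is what engages
the chaotic exploration.  State persistence across trials is available
(`persist_state`) but off by default.  Weights start uniform in
$[0, 1]$, as the experiments specify, and are never clipped — the
bounded gains limit per-step changes intrinsically.

**Zero-point outcomes.**  In the classification task the non-paying
outcome is coded $r = 0$ and *does* generate a prediction error and
update (default).  `zero_outcome_update = FALSE` treats such trials as
non-events instead; this alternative makes control agents' reward and
punishment optimality near-identical but removes the medication-driven
reward recovery, and is provided for sensitivity analysis.

**Reversal stage criterion.**  "Correct responses in the range 5-9" is
read as: each stage draws a criterion $k \sim U\{5..9\}$ and ends after
$k$ cumulative correct responses (`criterion_mode = "consecutive"`
implements the stricter alternative).  Blocks always run exactly 120
trials; exhausted reversal budgets simply continue on the last
contingency so each agent contributes exactly 480 trials.

**Complementary weights.**  The reversal task's design couples the four
D1 value entries as $w(s,a_1) = -w(s,a_2)$ and $w(s_1,a) = -w(s_2,a)$;
the package maintains a single free value that every update writes
through, so both identities hold to machine precision after every trial.

## What the simulations emulate — and what they do not

The three harnesses reproduce the *structure* of the behavioral
experiments: the six-state safe/risky juice schedule with its reward
base, the blocked reversal protocol with stimulus-repetition after
errors and condition-specific reversal signalling, and the four-image
probabilistic classification with its 80/20 outcome contingencies.
Populations of 100 seeded agents stand in for subject groups, and all
summary statistics are means with standard errors over agents.  They do
not model practice blocks, drink administration, subject covariates,
reaction times, or any within-trial timing beyond the 25-step selection
transient; passing simulations therefore speak to the model's
mechanisms under these idealized tasks, not to quantitative fits of
individual human or primate data.

A candid note on effect sizes: with the published gain tables, learning
rates and trial budgets, the serotonin effects on population behavior
are small in this implementation.  The risk task's safe-choice
proportion increases monotonically with $\alpha_{D1D2}$, but between the
published baseline (1.32) and depleted (0.0012) values the difference is
well under one percentage point, because the indirect-pathway risk term
($\alpha_{D1D2} \times \lambda^{GPi}_{D1D2} \times y_{D1D2} \approx
1.32 \times 0.05 \times 0.6$) is an order of magnitude below the
D2-pathway and STN-GPe variability.  Likewise, the reversal gains
(`table6`, $c_1 = 0.06$ for the D1 pool at $\eta = 0.01$) move weights
by $\sim 10^{-4}$ per trial, so within 120-trial blocks adaptation flows
through pathway gating rather than weight reversal, and in the
classification task the steep D1 gain ($c_2 = -50$) saturates at
$\pm\eta$ for any $|\delta| > 0.1$, making zero-point and punishment
outcomes indistinguishable to plasticity until weights have decayed to
near zero.  The sweep machinery (`sweep_experiment()`,
`experiment_evaluator()`) makes these sensitivities easy to map; the
$\alpha_{D1D2}$ and $\alpha_{D2}$ directions dominate the $\alpha_{D1}$
direction, consistent with the model's design.

## Numerical choices

Softmax probabilities are computed with max-subtraction; exact ties in
the thalamic argmax are broken uniformly at random from the agent's
stream.  Explicit Euler is used throughout with the published step
sizes; activations are checked for finiteness each decision and a
diagnostic error names the offending drives.  All randomness flows
through a two-level hierarchy (`derive_seeds()`): a master seed draws
per-agent seeds, each agent runs its entire trial sequence on its own
stream, and conditions and sweep points re-use the same per-agent seeds
(common random numbers), so every summary is bit-reproducible and
between-condition contrasts are paired.

Problem sizes used by the shipped tests and the results script: 100
agents per condition for the three experiments (matching the published
population size), 10,000 updates per probability for the risk-estimator
checks, and 15-25 agents per sweep point for sensitivity analyses.

## Parameter search

`fit_experiment()` reproduces the calibration workflow: a weighted
sum-of-squares objective between simulated and target summary
statistics, minimized by grid search or a small real-coded genetic
algorithm (tournament selection of 3, uniform blend crossover, Gaussian
mutation, elitism of 1; defaults 24 x 40 evaluations).  The published
optimizer's option set is not public, so these defaults are desk-scale
and deliberately non-canonical; the shipped presets use the published
constants directly rather than re-fitted ones.

## Known limitations

* No spiking or conductance-level dynamics; MSN pools are single gains.
* No phasic serotonin; the $\alpha$'s are tonic multipliers.
* Receptor heteromer kinetics, striosome-matrisome structure, and
  acetylcholine/norepinephrine modulation are out of scope.
* Multi-step (discounted) tasks are supported by the abstract module
  only; all shipped experiments are single-step.

## A short session

```{r example, eval = FALSE}
library(bgutility)

# variance tracking by the co-expressing pool
risk_tracking_demo(p_values = c(0.1, 0.3, 0.5, 0.7, 0.9))

# the risk-sensitivity experiment at a reduced population size
res <- run_risk_experiment(n_agents = 20, master_seed = 1)
print(res)

# a PD classification run from the packaged preset
cfg <- load_run_config(system.file("presets", "pd_classification.yaml",
                                   package = "bgutility"))
cfg$n_agents <- 20
run_from_config(cfg)
```
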