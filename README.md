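# bgutility

Mechanistic simulation of reward-punishment-risk based decision making
in the basal ganglia, with dopamine and serotonin as the controlling
neuromodulators.

The package is for computational neuroscientists who want to simulate
(and perturb) how the striatum and its downstream nuclei could compute
not just the *value* of an action but also its *risk*, and how serotonin
levels shift the balance between the two.  It implements two coupled
levels of description:

* **An abstract risk-sensitive reinforcement learner.**  A value table
  `Q` trained by temporal-difference learning (`δ = r − Q`), a risk
  table `h` trained by the risk prediction error `ξ = δ² − h` (fixed
  point: the outcome variance), and decisions by softmax over the
  utility

  ```
  U = Q − α · sign(Q) · h
  ```

  — risk-averse for gains, risk-seeking for losses, with `α` the
  serotonin correlate.

* **A basal ganglia network model.**  Three striatal medium-spiny-neuron
  pools (D1R, D2R, and D1R-D2R co-expressing) whose cortico-striatal
  weights learn through sigmoidal dopamine gain functions `λ(δ)`; the
  co-expressing pool's gain is the sum of a D1-like and a D2-like
  component and is therefore "U"-shaped in `δ`, which lets it track
  variance.  Direct ("Go") and indirect ("NoGo"/"Explore") pathways are
  gated by a second dopamine signal — the trial-to-trial utility
  gradient `δ_U` — and competed through an STN-GPe loop whose chaotic
  transients provide exploration; the thalamic channel with the largest
  integrated activation is executed.  Serotonin enters as three
  multipliers (`α_D1`, `α_D2`, `α_D1D2`) on the pathway drives, and
  Parkinson's disease as a clamp on the dopamine signal
  (`δ ≤ δ_Lim`, plus a medication increment `δ_Med` when ON).

Three behavioral experiment harnesses are included, each simulating a
population of 100 seeded agents: a safe/risky juice-reward task
(risk sensitivity under tryptophan depletion), a reversal-learning task
with deterministic reward/punishment outcomes (punishment-mediated
behavioral inhibition), and a four-image probabilistic classification
task (reward vs punishment learning in PD ON/OFF medication states).
Parameter sweep and genetic-algorithm calibration utilities, YAML run
configurations with shipped presets, and a thin command-line wrapper
(`inst/cli/bgsim.R`) round out the toolkit.

## A worked example

Variance tracking by the co-expressing pool — the package's core claim
in one call:

```r
library(bgutility)
risk_tracking_demo(p_values = c(0.1, 0.3, 0.5, 0.7, 0.9),
                   n_trials = 1500, seed = 4)
#>     p variance         y_d1     y_d1d2 h_abstract
#> 1 0.1     0.09 5.753603e-05 0.07703437 0.08943991
#> 2 0.3     0.21 1.380157e-01 0.25813705 0.22844814
#> 3 0.5     0.25 2.134638e-01 0.37072697 0.26620348
#> 4 0.7     0.21 7.536251e-01 0.23054758 0.23116495
#> 5 0.9     0.09 9.801597e-01 0.07532473 0.11085500
```

Across Bernoulli reward probabilities `p`, the D1R read-out `y_d1`
increases with the reward rate (its saturating gain places the fixed
point near the median rather than the mean), the abstract risk estimate
`h_abstract` converges to the analytic variance `p(1−p)`, and the
co-expressing network read-out `y_d1d2` follows the same inverted-U
shape — peaked at `p = 0.5`, vanishing toward the deterministic
extremes — which is what qualifies that pool as a cellular substrate
for risk.

A population experiment (here at a reduced size for speed):

```r
res <- run_risk_experiment(n_agents = 20, master_seed = 1)
print(res)
#> <bg_experiment 'risk'; master seed 1>
#>  condition    statistic  mean      se  n
#>   baseline safe_overall 0.560 0.00841 20
#>   baseline     safe_eev 0.366 0.01190 20
#>   baseline     safe_uev 0.754 0.00711 20
#>   baseline    safe_gain 0.952 0.01070 20
#>   baseline    safe_loss 0.364 0.00948 20
#>        rtd safe_overall 0.549 0.00696 20
#>        rtd     safe_eev 0.358 0.00636 20
#>        rtd     safe_uev 0.739 0.01250 20
#>        rtd    safe_gain 0.943 0.01850 20
#>        rtd    safe_loss 0.352 0.00559 20
```

`safe_*` columns are proportions of safe-target choices (overall, over
equal- and unequal-expected-value states, and over gain/loss states
relative to the 159.83 ms reward base), as mean ± standard error over
agents.  Agents strongly prefer the safe target when it is the
higher-mean (gain) option and the risky target in loss states — the
gain/loss risk-attitude asymmetry carried by the `sign(Q)` term.

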