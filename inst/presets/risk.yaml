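# Risk-sensitivity experiment: safe vs risky juice targets.
# Striatal gains: table5; GPi gains: table3; reward base 159.83 ms.
experiment: risk
n_agents: 100
master_seed: 1
trials_per_state: 50
reward_base: 159.83
eta:
  d1: 0.3
  d2: 0.1
  d1d2: 0.1
conditions:
  baseline:
    alpha_d1: 1
    alpha_d2: 1
    alpha_d1d2: 1.32
  rtd:
    alpha_d1: 1
    alpha_d2: 1
    alpha_d1d2: 0.0012
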