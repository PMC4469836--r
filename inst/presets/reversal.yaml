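# Reversal learning under tryptophan depletion.
# Striatal gains: table6; GPi gains: table3.
experiment: reversal
n_agents: 100
master_seed: 1
block_trials: 120
max_reversals: 16
eta:
  d1: 0.01
  d2: 0.01
  d1d2: 0.01
conditions:
  balanced:
    alpha_d1: 1
    alpha_d2: 5
    alpha_d1d2: 1
  depleted:
    alpha_d1: 1
    alpha_d2: 2.25
    alpha_d1d2: 1
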