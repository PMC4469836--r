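# Probabilistic reward-punishment classification in Parkinson's disease.
# Striatal gains: table8; GPi gains: table3.
experiment: pd_classification
n_agents: 100
master_seed: 1
n_blocks: 4
trials_per_image_block: 10
eta:
  d1: 0.01
  d2: 0.1
  d1d2: 0.1
conditions:
  control:
    alpha_d1: 1
    alpha_d2: 1
    alpha_d1d2: 0.2
  pd_off:
    status: pd_off
    delta_lim: 0.001
    alpha_d1: 1
    alpha_d2: 0.99
    alpha_d1d2: 0.001
  pd_on:
    status: pd_on
    delta_lim: 0.001
    delta_med: 0.021
    alpha_d1: 1
    alpha_d2: 0.2
    alpha_d1d2: 0.001
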