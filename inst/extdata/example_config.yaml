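# Example run configuration: four residence-time experiments at the default
# 50 degrees C rate constants, 1% relative Gauss-Markov error.
kinetics:
  k: [0.049, 0.109, 0.211, 1.213, 2.407, 0.069]
  residence_times_s: [200, 500, 1000, 2000]
  c_tg0_M: 1.0
  c_meoh0_M: 0.023
  t_end_s: 3000
  dt_s: 30
noise:
  epsilon: 0.01
  tau_s: 30
  variance_mode: relative
  seed: 1
  levels: [0, 0.01, 0.025, 0.05, 0.075, 0.10]
study:
  n_replicates: 100
  base_seed: 1
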