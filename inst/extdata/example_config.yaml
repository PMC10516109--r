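# Example analysis configuration: a 2-feature, 2-level code with two
# simultaneously presented stimuli, and a synthetic-session block.
theory:
  K: 2
  n: 2
  S: 2
  dLV: 1.0
  dLA: 0.8
  dN: 0.6
  sigma: 0.5
  epsilon: 0.0
session:
  n_neurons: 60
  n_trials: 800
  heterogeneity: 0.1
  seed: 1
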