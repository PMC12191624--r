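# Diamond with the YB -> Z link inhibitory; no prototype states exist.
variables: [X, YA, YB, Z]
links:
  - [X, YA, generative]
  - [X, YB, generative]
  - [YA, Z, generative]
  - [YB, Z, inhibitory]
params:
  root_prior: {X: 0.673}
  link_weight: {generative: 0.732, inhibitory: -0.441}
  exo_weight: 0.389
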