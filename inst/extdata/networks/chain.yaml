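# Three-variable chain: X -> Y -> Z, both links generative.
variables: [X, Y, Z]
links:
  - [X, Y, generative]
  - [Y, Z, generative]
params:
  root_prior: {X: 0.6}
  link_weight: {generative: 0.8}
  exo_weight: {Y: 0.3, Z: 0.3}
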