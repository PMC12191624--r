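# Four-variable diamond, all links generative; the all-generative study
# condition. Parameters are the condition's average fitted values.
variables: [X, YA, YB, Z]
links:
  - [X, YA, generative]
  - [X, YB, generative]
  - [YA, Z, generative]
  - [YB, Z, generative]
params:
  root_prior: {X: 0.649}
  link_weight: {generative: 0.476}
  exo_weight: 0.454
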