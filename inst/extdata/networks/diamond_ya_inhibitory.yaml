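# Diamond with the YA -> Z link inhibitory; no prototype states exist.
variables: [X, YA, YB, Z]
links:
  - [X, YA, generative]
  - [X, YB, generative]
  - [YA, Z, inhibitory]
  - [YB, Z, generative]
params:
  root_prior: {X: 0.736}
  link_weight: {generative: 0.714, inhibitory: -0.395}
  exo_weight: 0.44
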