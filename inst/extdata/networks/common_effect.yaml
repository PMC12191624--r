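# Three-variable common effect: CA -> E <- CB, both links generative.
variables: [CA, CB, E]
links:
  - [CA, E, generative]
  - [CB, E, generative]
params:
  root_prior: {CA: 0.6, CB: 0.6}
  link_weight: {generative: 0.8}
  exo_weight: {E: 0.3}
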