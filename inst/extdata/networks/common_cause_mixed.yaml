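# Common cause with one inhibitory arm: C -> EA generative, C -> EB
# inhibitory. Prototype states are 110 and 001.
variables: [C, EA, EB]
links:
  - [C, EA, generative]
  - [C, EB, inhibitory]
params:
  root_prior: {C: 0.6}
  link_weight: {generative: 0.8, inhibitory: -0.8}
  exo_weight: {EA: 0.3, EB: 0.3}
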