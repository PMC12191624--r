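# Three-variable common cause: EA <- C -> EB, both links generative.
# Exogenous weights left untied (wEA, wEB) for the three-variable fixtures.
variables: [C, EA, EB]
links:
  - [C, EA, generative]
  - [C, EB, generative]
params:
  root_prior: {C: 0.6}
  link_weight: {generative: 0.8}
  exo_weight: {EA: 0.3, EB: 0.3}
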