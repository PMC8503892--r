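seed: 11
stages: [simulate, normalize, classify]
simulate:
  groups: {PFA: 8, PFB: 4}
  signature_fold: 6
classify:
  compartment: PF
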