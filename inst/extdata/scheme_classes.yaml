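wt:
  K1: 0.01
  K2_uM: 200
  gamma: 25
  K5: 0.1
  PT_uM: 50
  LT_uM: 150
moderate:
  K1: 0.15
  K2_uM: 200
  gamma: 125
  K5: 0.5
  PT_uM: 50
  LT_uM: 150
severe:
  K1: 1
  K2_uM: 200
  gamma: 2500
  K5: 10
  PT_uM: 50
  LT_uM: 150
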