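LEMlike:
  alpha_x: 0.1
  beta_x: 0.05
  clinical_scale: 1.0
  table: LEMlike.csv
MKMlike:
  alpha_x: 0.1
  beta_x: 0.05
  clinical_scale: 1.0
  table: MKMlike.csv
NIRSlike:
  alpha_x: 0.1
  beta_x: 0.05
  clinical_scale: 0.8794
  table: MKMlike.csv
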