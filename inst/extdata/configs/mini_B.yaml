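name: mini.B
case: mini
phantom:
  dims:
  - 20.0
  - 20.0
  - 12.0
  spacing: 3.0
  ctv:
    shape: box
    size:
    - 18.0
    - 18.0
    - 18.0
  oars:
  - name: OAR
    shape: box
    center:
    - 30.0
    - 42.0
    - 18.0
    size:
    - 18.0
    - 9.0
    - 18.0
beams:
- spot_spacing: 6.0
  layer_spacing: 5.0
  sigma_lateral: 4.0
  direction: +x
- spot_spacing: 6.0
  layer_spacing: 5.0
  sigma_lateral: 4.0
  direction: -x
curve: []
margin: 4.0
models: default
scenario:
  scenario: B
  target_models: NIRSlike
  oar_model: LEMlike
  prescriptions:
    LEMlike: 66.4
    NIRSlike: 57.6
  fractions: 16
oar_constraints:
- roi: OAR
  kind: max_dose
  limit: 50.0
priorities:
  target: 1.0
  oar: 0.3
goals:
- roi: CTV
  model: LEMlike
  metric: V
  level: 63.08
  limit: 95.0
  cmp: '>='
- roi: CTV
  model: LEMlike
  metric: HI
  limit: 17.0
  cmp: <=
- roi: CTV
  model: NIRSlike
  metric: V
  level: 54.72
  limit: 95.0
  cmp: '>='
- roi: CTV
  model: NIRSlike
  metric: HI
  limit: 17.0
  cmp: <=
- roi: OAR
  model: LEMlike
  metric: D_pct
  volume: 2.0
  limit: 60.0
  cmp: <=
solver:
  max_iter: 300
  grad_tol: 1.0e-05
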