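name: piecewise_eq6_10
calibration:
  slope: 0.0008
  intercept: 0.0
  output: rho_ct
conversions:
- scale: 0.877
  offset: 0.08
  pre_scale: 1.15
  output: rho_ash
modulus:
- lo: 0.0
  hi: 0.3
  a: 33900.0
  b: 2.2
- lo: 0.3
  hi: 0.486
  constant: 2398.0
- lo: 0.486
  hi: .inf
  a: 10200.0
  b: 2.01
rho_floor: 0.001
e_floor: 0.01
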