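name: hgbg
model_spec:
- HG
- BG
intercept: -724.809999999999945
genotype_effect:
  BS: 0.0
  FV: -101.069999999999993
  FV_RH_m: -121.049999999999997
  FV_RH_h: -148.330000000000013
  HF: -16.417999999999999
parity_effect:
  P5plus: 0.0
  P1: -16.797000000000001
  P2: -7.0643
  P3_4: -0.9199
pooled_slope:
  HG: 3.1643
  BG: 2.9949
genotype_slope:
  HG:
    BS: 0.0
    FV: 1.0631
    FV_RH_m: 1.1516
    FV_RH_h: 0.716
    HF: -0.0485
  BG:
    BS: 0.0
    FV: -0.3853
    FV_RH_m: -0.3985
    FV_RH_h: -0.01813
    HF: 0.00439
lactation_curve:
- 2.7426
- -0.324907
- 0.00231406
- -5.67999e-06
- 4.74719e-09
dry_curve:
- 18.754999999999999
- 0.254644

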