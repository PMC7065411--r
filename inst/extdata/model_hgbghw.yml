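name: hgbghw
model_spec:
- HG
- BG
- HW
intercept: -833.389999999999986
genotype_effect:
  BS: 0.0
  FV: -79.984999999999999
  FV_RH_m: -133.550000000000011
  FV_RH_h: -121.769999999999996
  HF: 0.7205
parity_effect:
  P5plus: 0.0
  P1: -9.462899999999999
  P2: -4.6182
  P3_4: -2.2144
pooled_slope:
  HG: 2.5192
  BG: 2.903
  HW: 4.7367
genotype_slope:
  HG:
    BS: 0.0
    FV: 0.9442
    FV_RH_m: 1.2656
    FV_RH_h: 0.8393
    HF: 0.00328
  BG:
    BS: 0.0
    FV: -0.4459
    FV_RH_m: -0.475
    FV_RH_h: -0.0904
    HF: 0.03483
  HW:
    BS: 0.0
    FV: 0.3378
    FV_RH_m: 0.1046
    FV_RH_h: -0.6885
    HF: -0.6804
lactation_curve:
- -0.390321
- -0.00278743
- 0.00231406
- -7.38974e-06
- 7.23071e-09
dry_curve:
- 17.260200000000001
- 0.226024

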