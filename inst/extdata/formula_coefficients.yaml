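# Formula coefficient registry (mirrors the packaged defaults).
# Cockcroft-Gault: umol/L serum-creatinine dialect; for the mg/dL "x72"
# dialect set factor_male: 1.0, factor_female: 0.85 and pre-convert scr.
cockcroft_gault:
  factor_male: 1.23
  factor_female: 1.04
  age_anchor: 140
devine_ibw:
  base_male: 50
  base_female: 45.5
  slope_per_inch: 2.3
  height_anchor_cm: 152.4
dubois_bsa:
  coef: 0.007184
  exp_weight: 0.425
  exp_height: 0.725
# Chatelut-type direct carboplatin clearance with the Benezet
# min(ABW, IBW) weight substitution.
benezet:
  intercept_per_kg: 0.134
  slope: 218
  age_coef: 0.00457
  female_coef: 0.314
# Cystatin-C carboplatin clearance power model (direct clearance).
schmitt:
  typical_cl: 110
  scr_ref: 75
  scr_exp: -0.512
  cysc_ref: 1.0
  cysc_exp: -0.327
  weight_ref: 65
  weight_exp: 0.474
  age_ref: 56
  age_exp: -0.387
  female_factor: 0.854
# 2021 race-free CKD-EPI equations (eGFR in mL/min/1.73 m^2).
ckdepi_2021_cr:
  base: 142
  kappa_female: 0.7
  kappa_male: 0.9
  alpha_female: -0.241
  alpha_male: -0.302
  exp_high: -1.200
  age_decay: 0.9938
  female_factor: 1.012
ckdepi_2021_crcys:
  base: 135
  kappa_female: 0.7
  kappa_male: 0.9
  alpha_female: -0.219
  alpha_male: -0.144
  exp_high: -0.544
  cysc_knot: 0.8
  cysc_exp_low: -0.323
  cysc_exp_high: -0.778
  age_decay: 0.9961
  female_factor: 0.963
units:
  scr_umol_per_mgdl: 88.4
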