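cvd_risk:
  age_low:
  - 18.0
  - 45.0
  - 55.0
  - 65.0
  - 75.0
  - 85.0
  age_high:
  - 44.0
  - 54.0
  - 64.0
  - 74.0
  - 84.0
  - -1.0
  mean:
  - 0.0015
  - 0.0071
  - 0.0149
  - 0.0266
  - 0.0478
  - 0.0681
  se:
  - 0.0004
  - 0.0018
  - 0.0037
  - 0.0067
  - 0.012
  - 0.017
rr_cvd_prior: 1.965
p_anxiety_base: 0.18
rr_anx_cvd: 1.66
rr_cvd_noise: 1.14
rr_anx_noise: 1.79
anxiety_odds_ratio: 2.0
cost_cvd_direct: 23229.0
cost_cvd_indirect: 12837.0
cost_anx_direct: 2814.0
cost_anx_indirect: 313.0
exposure_op_cost_pp: 1516.0
exposure_prod_loss_pp: 238.0
disutil_cvd_event: 0.283
disutil_anxiety: 0.16
u_prior_cvd: 0.844
u_no_cvd: 1.0
cvd_prevalence_init: 0.35
cvd_case_fatality: ~
prior_cvd_mortality_multiplier: 1.0
start_age: 41.0
discount_rate: 0.03
population_60db: 83807.0
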