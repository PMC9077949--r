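elst:
  t_short: 0.69999999999999996
  t_long: 3.75
  t_ascend: 5.5
  s_seams:
  - 110.0
  - 150.0
  s_slopes:
  - 0.20000000000000001
  - 0.10000000000000001
  - 0.05
  s_intercepts:
  - -39.5
  - -28.5
  - -21.0
xswitch:
  t_min: 6.0
  slope: 0.26000000000000001
  turn: 30.0
  gauss_width: 10.0
  gauss_amp: 1.0
yswitch:
  t_const: 10.0
  seam_low: 15.34999999999999964
  seam_high: 100.0
  poly:
  - 3.70116436186053699
  - -1.43128120222996591
  - 0.17602017800781239
  - -0.00496547153000631
  - 6.52047844249566794e-05
  - -4.40817281065703217e-07
  - 1.48416629083439494e-09
  - -1.96709721335559917e-12
  lin_slope: 0.2399
  lin_intercept: 34.8089999999999975
bst:
  mu_coeff: 5.00000000000000024e-05
  dead_time: 0.2228
burst:
  fractions:
  - 0.60899999999999999
  - 0.33000000000000002
  - 0.061
  n_burst: 3.0
efficiency:
  lin_slope: 0.001971
  lin_intercept: -0.1084
  seam: 123.0
  poly:
  - 34.91785611467123118
  - -0.98453294827240589
  - 0.01098029030171986
  - -6.04889212211066619e-05
  - 1.6508890465662399e-07
  - -1.78925440070434688e-10
pulse_period_ms: 1.0
pulse_duration_us: 7.0
mu_min: 0.01
energy_range:
- 70.0
- 227.0
spill_rate_mu_s: ~
label: synchrocyclotron-pbs
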