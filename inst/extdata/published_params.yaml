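# Final population estimates of the combination-therapy K-PD model.
# Flat key-value layout; keys match the pop_params() fields. k_cd8 is tied to
# k_ag structurally and is therefore not listed. Units: volumes mm^3, rate
# constants day^-1, theta_cd8 au^-1 day^-1, effect slopes au^-1, sigma_log on
# log(mm^3); omegas are SDs of log-normal random effects (dimensionless).
params:
  ts0: 19.5
  lam: 0.194
  k_ag: 4.93
  k_pic: 0.721
  k_apd1: 2.3e-3
  theta_cd8: 1.63
  theta_pic: 1200.0
  theta_apd1: 821.0
  resistance: 1.0
  sigma_log: 0.597
  omega_lam: 0.557
  omega_theta_cd8: 1.24
  omega_k_pic: 3.17
  omega_k_apd1: 5.16
# 90% non-parametric bootstrap confidence intervals (5th-95th percentiles)
# for the two K-PD rate constants varied in the grid-exploration study.
ci90:
  k_pic: [0.347, 4.194]
  k_apd1: [6.43e-5, 9.09e-3]
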