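# Shared fixtures: small designs and parameter sets built in code.

# single-arm design with a configurable animal count
one_arm_design <- function(arm, n, ...) {
  des <- default_design(...)
  des$arms <- tibble::tibble(arm = arm, n_animals = as.integer(n))
  des
}

# dosing schedule of the triple-therapy arm
triple_doses <- function() {
  dose_events(c("Ag", "Ag", "PIC", "PIC", "aPD1", "aPD1", "aPD1"),
              c(7, 14, 7, 14, 7, 10, 14))
}

# control-arm generating truth: published growth parameters with the
# control-fit lambda CV of 13.5%
control_truth <- function() {
  pop_params(ts0 = 19.5, lam = 0.194,
             omega_lam = sqrt(log(1 + 0.135^2)), sigma_log = 0.597)
}

# antigen+PIC-as-one-compound truth: published theta_cd8 with its
# intermediate-fit IAV of 46%
single_compound_truth <- function() {
  pop_params(ts0 = 19.5, lam = 0.194, k_ag = 4.93, theta_cd8 = 1.63,
             omega_theta_cd8 = sqrt(log(1 + 0.46^2)), sigma_log = 0.597)
}
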