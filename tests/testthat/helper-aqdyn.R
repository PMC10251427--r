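# Shared fixtures and an independent oracle for the linear regime.

default_model <- function(kappa_hyd = 0.99, kappa_drug = 0.33) {
  calibrate(baseline_physiology(), drug_regimen(),
            kappa_hyd = kappa_hyd, kappa_drug = kappa_drug)
}

UL_MIN <- 1e-9 / 60  # m^3/s per uL/min

# Closed-form steady-state IOP for the linear (kappa_hyd = 0) regime, written
# directly from the baseline physiology numbers and elementary algebra --
# independent of the package's calibration and solver code paths.
oracle_linear_iop <- function(eta, m_abs = 0, kappa_drug = 0.33) {
  p_ac <- 1950 / 133.322
  q_conv <- 2.45 * UL_MIN
  q_unc <- 0.3 * UL_MIN
  q_bar <- q_conv + q_unc
  L_ac <- q_bar / (15 - p_ac)
  L_cb <- q_conv / (p_ac - 8)
  L_ub <- q_unc / (p_ac - 11)
  P_b <- 11 + q_bar / L_ac
  R_cv <- eta / L_cb
  P_t <- 8 + (R_cv + 1 / L_ac) * q_bar
  k_drug <- 0.5 * 0.05 * 1.5625 * 14
  q_drug <- kappa_drug * 7.87e-11 * m_abs^4 / (m_abs^4 + k_drug^4)
  phi <- R_cv * L_ub
  (P_t - R_cv * q_drug + P_b * phi) / (1 + phi)
}
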