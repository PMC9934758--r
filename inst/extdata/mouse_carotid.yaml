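# Mouse common carotid artery baseline.
# Kinetic rates from literature-derived turnover estimates; wall, tone and
# material constants from the passive+active pressure-diameter calibration.
kinetics:
  beta1: 0.7            # secreted fraction of synthesized procollagen
  beta2: 0.2            # maturation (cross-linking) rate, 1/day
  mu1: 0.1              # intermediate removal rate, 1/day
  mu2: 0.01             # mature removal rate, 1/day (mean fiber age 100 d)
  MW: 4.981617e-22      # collagen molecular weight, kg
  a_max: 350            # maximum tracked cohort age, day
wall:
  r_oh_mm: 0.328
  h_h_um: 21.2
  alpha_h_deg: 47.6
  G_hc: 1.07
  G_hm: 1.25
  G1e: 2.19
  G2e: 1.64
  c1e: 657.9
  c2c: 3090.0
  c3c: 18.9
  c1m: 103.0
  c2m: 11.5
  c3m: 0.794
  sigma_h_kPa: 120.0
  tau_wh_Pa: 1.5
  P_h_mmHg: 102.0
  phi0_e: 0.06
  phi0_m: 0.09
  phi_f: 0.70
  phi0_k: [0.016650, 0.005235, 0.064050, 0.064050]  # axial, circ, +/-diag
  rho_wall: 1050.0
  collagen_compression: as_printed
tone:
  S_basal: 0.862
  k_ton: 17.333333333333332   # shear gain / 3
  lambda_M: 1.65
  lambda_0: 0.65
  K_act: 0.10
  tone_offset: 0.4054651081081644   # ln(3/2)
gains:
  K_sigma_c: 2.0
  K_sigma_m: 2.0
  K_tau_c: 52.0
  K_tau_m: 52.0
  K_mu1: 0.01
  K_mu2: 0.01
  zeta_c: 1.0
numerics:
  dt: 0.1
  duration: 300.0
  output_interval: 1.0
  newton_tol: 1.0e-9
  newton_max_iter: 100
  fd_step: 1.0e-7
  equilibrium_radius: inner
  sigma_c_stimulus: fiber
  sigma_m_stress: total
  balance: s_basal
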