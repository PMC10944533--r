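# Figure-parameter presets (versioned configuration).
# Units: dissociation constants in molecules, rates relative to beta = 1.
# Calibrated once against the published sensitivity of each switch; see the
# package vignette for the calibration rationale.
cooperative:
  architecture: cooperative_binding
  K_r: 20.0
  c: 0.1
  alpha: 20.0
  beta: 1.0
  k_on: 0.1
cooperative_noncooperative:
  architecture: cooperative_binding
  K_r: 20.0
  c: 1.0
  alpha: 20.0
  beta: 1.0
  k_on: 0.1
sequestration_strong:
  architecture: sequestration
  K_a: 0.5       # Ka_tilde = 5e-3
  K_s: 0.0025    # Ks_tilde = 2.5e-5
  A_T: 100
  alpha: 20.0
  beta: 1.0
  k_on: 0.1
sequestration_weak:
  architecture: sequestration
  K_a: 1000.0    # Ka_tilde = 10
  K_s: 0.0025
  A_T: 100
  alpha: 20.0
  beta: 1.0
  k_on: 0.1
sequestration_blocking:
  architecture: sequestration_blocking
  K_a: 0.5
  K_s: 0.0025
  K_b: 1.0       # Kb_tilde = 0.01
  A_T: 100
  alpha: 20.0
  beta: 1.0
  k_on: 0.1
sequestration_blocking_displacement:
  architecture: sequestration_blocking_displacement
  K_a: 0.05      # Ka_tilde = 5e-4
  K_s: 0.001     # Ks_tilde = 1e-5
  K_b: 1.0
  K_d: 1000.0    # Kd_tilde = 10
  A_T: 100
  alpha: 20.0
  beta: 1.0
  k_on: 0.1
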