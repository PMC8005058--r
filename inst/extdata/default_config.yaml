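seed: 1
chip:
  n_outputs: 8
  arm_length_mm: 12.5
  asym_length_mm: 0.240833333333333
  lambda_res_nm: 850.0
  n_eff: 1.55
  dneff_dlambda_per_nm: -0.000529411764706
  sensitivity_override_nm_riu: 5000.0
  bulk_sensitivity_nm_riu: 500.0
sweep:
  sweep_rate_hz: 10.0
  samples_per_cycle: 1000
  sweep_span_pm: 3000.0
  center_wavelength_nm: 850.0
noise:
  sigma_ampl_pm: 0.1539600717839
  sigma_spect_pm: 0.1539600717839
  sigma_temp_pm: 0.1539600717839
instrument:
  gain: 1.0
  offset: 0.1
  temp_tau_cycles: 5.0
  instrument_mode: no
assay:
  dt_s: 0.1
  mixing_tau_s: 5.0
  transport_delay_s: 15.0
  control_drift_rate_pm_s: -1.0
  serum_background_rate_pm_s_per_pct: 0.03
  channels:
  - amzi_index: 1
    sensing_arm_probe: anti-TGFBI
    reference_arm_probe: mIgG
  - amzi_index: 2
    sensing_arm_probe: none
    reference_arm_probe: mIgG
  - amzi_index: 3
    sensing_arm_probe: anti-TGFBI
    reference_arm_probe: mIgG
  - amzi_index: 4
    sensing_arm_probe: none
    reference_arm_probe: mIgG
  - amzi_index: 5
    sensing_arm_probe: anti-POSTN
    reference_arm_probe: mIgG
  - amzi_index: 6
    sensing_arm_probe: anti-POSTN
    reference_arm_probe: mIgG
  models:
    TGFBI:
      k_on: 100000.0
      k_off: 0.0001
      surface_capacity_shift_pm: 2000.0
      molar_mass_g_mol: 68000.0
      nonspecific_rate_pm_s_per_ng_ml: 2.0e-05
      crossreact_threshold_ng_ml: .inf
      crossreact_rate_pm_s_per_ng_ml: 0.0
    POSTN:
      k_on: 100000.0
      k_off: 0.0001
      surface_capacity_shift_pm: 2000.0
      molar_mass_g_mol: 90000.0
      nonspecific_rate_pm_s_per_ng_ml: 2.0e-05
      crossreact_threshold_ng_ml: 1000.0
      crossreact_rate_pm_s_per_ng_ml: 0.0002
  program: []
analysis:
  baseline_window_s:
  - 0.0
  - 10.0
  contrast_floor: 0.01
  settle_fraction: 0.4
  detect_k: 5.0
  min_threshold_pm: 0.5
  settling_guard_s: 20.0
  qc_bound_pm: 25.0
  lod_channel: 1
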