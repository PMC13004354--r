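{
  "effective_resistance_model3219_1e12_Pa_s_m3": 8.43,
  "tip_resistance_share_pct": 95,
  "flow_model3219_6psi_ul_s": 0.82,
  "tip_velocity_model3219_6psi_cm_s": 21,
  "ambient_30mmHg_equivalent_psi": 0.58,
  "pressure_500hPa_psi": 7.25,
  "min_syringe_pressure_psi": 5,
  "min_syringe_pressure_tol_psi": 1,
  "min_flow_pressure_psi": 6,
  "jet_constant_published_fit": 45.8,
  "bench_jet_speed_6psi_cm_s": 0.12,
  "injection_time_s": 5,
  "recommended_pause_range_s": [30, 75],
  "bc_residual_6psi_range_s": [27, 28],
  "bc_residual_20psi_range_s": [47, 48]
}
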