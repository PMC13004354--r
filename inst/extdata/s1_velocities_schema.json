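{
  "name": "s1_velocities",
  "description": "Mean exit velocity (cm/s) of a water solution (1 mPa.s) at machine pressures 6-20 psi for the three commercial cannula setups. The published supplementary table's cell values are not available in text form; load_fixture() supplies a model-computed stand-in flagged as synthetic.",
  "columns": [
    {"name": "system", "type": "character"},
    {"name": "pressure_psi", "type": "numeric", "unit": "psi"},
    {"name": "mean_velocity_cm_s", "type": "numeric", "unit": "cm/s"}
  ],
  "standin": "computed from the hydraulic model at load time (synthetic)"
}
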