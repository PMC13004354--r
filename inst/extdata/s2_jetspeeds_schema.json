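{
  "name": "s2_jetspeeds",
  "description": "Jet speed (cm/s +/- sd) at machine pressures 6-20 psi for the 5 mm 41g cannula setup. The published supplementary table's cell values are not available in text form; load_fixture() supplies a synthetic stand-in generated by the calibrated jet model with the default generator settings.",
  "columns": [
    {"name": "pressure_psi", "type": "numeric", "unit": "psi"},
    {"name": "condition", "type": "character", "levels": ["BC", "MP1", "MP2", "MP3"]},
    {"name": "jet_speed_cm_s", "type": "numeric", "unit": "cm/s"},
    {"name": "sd_cm_s", "type": "numeric", "unit": "cm/s"}
  ],
  "standin": "generated by the synthetic bench-rig generator at load time (synthetic)"
}
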