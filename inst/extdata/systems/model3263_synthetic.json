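{
  "name": "model3263",
  "min_pressure_psi": 5,
  "notes": "SYNTHETIC tip diameter: the 51g metal tip inner diameter is not published; 0.027989 mm is back-calculated from the published 20 psi flow-rate cell (2.57 ul/s) by quartic-root inversion of the series Poiseuille model. Do not treat as manufacturer ground truth.",
  "segments": [
    {
      "label": "5 cm short extension tube (Model 3223)",
      "inner_diameter_mm": 0.5,
      "length_mm": 150
    },
    {
      "label": "Proximal needle section",
      "inner_diameter_mm": 0.26,
      "length_mm": 35
    },
    {
      "label": "Distal metal 51g tip (Model 3263, 0.6 mm; derived diameter)",
      "inner_diameter_mm": 0.027989,
      "length_mm": 0.6
    }
  ]
}
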