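{
  "name": "model3255",
  "min_pressure_psi": 5,
  "segments": [
    {
      "label": "5 cm short extension tube (Model 3223)",
      "inner_diameter_mm": 0.5,
      "length_mm": 150
    },
    {
      "label": "Proximal needle section (Model 3219/3255)",
      "inner_diameter_mm": 0.26,
      "length_mm": 35
    },
    {
      "label": "Distal polyamide 41g tip (Model 3255, 2 mm)",
      "inner_diameter_mm": 0.071,
      "length_mm": 2
    }
  ]
}
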