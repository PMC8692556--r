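{
  "method_id": "pc_group",
  "formula_id": "inverse_sq",
  "property": "Pc_MPa",
  "comment": "Lydersen-type critical-pressure increments; assembled as Pc = 0.101325 * M / (0.34 + S)^2 with S the increment sum and M in g/mol (classic atm form converted to MPa).",
  "contributions": {
    "CH3": 0.227,
    "CH2": 0.227,
    "CH": 0.210,
    "C": 0.210,
    "=CH2": 0.198,
    "=CH": 0.198,
    "arCH": 0.154,
    "arC": 0.154,
    "OH": 0.060,
    "O": 0.160,
    "C=O": 0.290,
    "CHO": 0.330,
    "COOH": 0.400,
    "COO": 0.470,
    "NH2": 0.095,
    "NH": 0.135,
    "N": 0.170,
    "Cl": 0.320
  }
}
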