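{
  "method_id": "vol_group",
  "formula_id": "linear_sum",
  "property": "V_cm3_mol",
  "comment": "Fedors-type molar-volume increments (cm3/mol); assembled as V = sum of count * increment.",
  "contributions": {
    "CH3": 33.5,
    "CH2": 16.1,
    "CH": -1.0,
    "C": -19.2,
    "CH2=": 28.5,
    "CH=": 13.5,
    "phenyl": 71.4,
    "phenylene": 52.4,
    "OH": 10.0,
    "O": 3.8,
    "C=O": 10.8,
    "COOH": 28.5,
    "NH2": 17.5,
    "NH": 4.5,
    "N": -9.0,
    "Cl": 24.0
  }
}
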