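{
  "method_id": "tc_group",
  "formula_id": "tb_ratio",
  "property": "Tc_K",
  "comment": "Lydersen-type critical-temperature increments; assembled as Tc = Tb / (0.567 + S - S^2) with S the increment sum. Requires Tb (K).",
  "contributions": {
    "CH3": 0.020,
    "CH2": 0.020,
    "CH": 0.012,
    "C": 0.000,
    "=CH2": 0.018,
    "=CH": 0.018,
    "arCH": 0.011,
    "arC": 0.011,
    "OH": 0.082,
    "O": 0.021,
    "C=O": 0.040,
    "CHO": 0.048,
    "COOH": 0.085,
    "COO": 0.047,
    "NH2": 0.031,
    "NH": 0.031,
    "N": 0.014,
    "Cl": 0.017
  }
}
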