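{
  "intercept": 0.545,
  "coefficients": {
    "charge_difference": -2.5822,
    "ligand_logp": -0.4023,
    "analyte_logp": -0.4902,
    "ligand_tanimoto": -4.7748,
    "analyte_tanimoto": 0.6395
  },
  "provenance": "published AuNP-analyte scoring function v1; trained on 32 literature systems (dG -2.85..-8.71 kcal/mol); fingerprint dialect: openbabel-FP2-1024bit-path; references: phenol (analyte), heneicosanethiolate (ligand)",
  "checksum": "5f9aca37e0d66bfbced9c6d8c72d3873",
  "scaled_coefficients": {
    "charge_difference": -0.753,
    "ligand_logp": -0.581,
    "analyte_logp": -0.471,
    "ligand_tanimoto": -0.41,
    "analyte_tanimoto": 0.044
  }
}
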