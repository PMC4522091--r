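{
  "model": "toy_redox.json",
  "n_metabolites": 33,
  "n_reactions": 38,
  "objective_id": "BIOMASS",
  "isobutanol_exchange_id": "EX_iboh_e",
  "cofactor_reactions": ["ADHE", "BIOMASS", "ETC", "G6PDH_lump", "GAPD", "ILV_lump", "LDH", "PDH", "SUCC_lump", "THD", "YQHD"],
  "reference": {
    "growth": 1.5241635672,
    "isobutanol": 0.5,
    "nadh_flux_sum": 18.9776951403,
    "nadph_flux_sum": 7.096654269
  },
  "candidates": [
    {
      "id": "ADHE",
      "modes": "knockout",
      "v_ref": 0
    },
    {
      "id": "ETC",
      "modes": "knockout",
      "v_ref": 4
    },
    {
      "id": "G6PDH_lump",
      "modes": "overexpression",
      "v_ref": 3.5241636493
    },
    {
      "id": "GAPD",
      "modes": "cofactor_swap",
      "v_ref": 18.2156133567
    },
    {
      "id": "LDH",
      "modes": "knockout",
      "v_ref": 14.9293678417
    },
    {
      "id": "SUCC_lump",
      "modes": "knockout",
      "v_ref": 1.6410671962e-07
    },
    {
      "id": "THD",
      "modes": "knockout,overexpression",
      "v_ref": 0.048326970389
    }
  ],
  "top_ranked": [
    {
      "target_id": "GAPD",
      "mode": "cofactor_swap",
      "factor": 1,
      "f_ph": 142.9024391619
    }
  ],
  "note": "synthetic fixture: values computed with the package itself and frozen for consistency checks"
}
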