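{
  "label": "Lti30-like (synthetic representative)",
  "comment": "Six K-segment dehydrin. segment_lengths_aa are synthetic representatives spanning the 8-19 residue range of the inter-K linkers; net_positive_charge is inferred from electroneutral binding of 0.1 mol% protein to 5 mol% monovalent anionic lipid.",
  "segment_lengths_aa": [8, 11, 14, 17, 19],
  "n_k_segments": 6,
  "net_positive_charge": 50
}
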