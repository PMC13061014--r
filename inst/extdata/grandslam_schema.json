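{
  "gene_id": "Gene",
  "gene_name": "Symbol",
  "read_count": "Readcount",
  "conversions": "Conversions",
  "t_coverage": "Coverage",
  "ntr_map": "MAP",
  "ntr_mean": "Mean",
  "ntr_q05": "lower",
  "ntr_q95": "upper"
}
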