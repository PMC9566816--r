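{
  "dataset": "Breast cancer (Wisconsin original, breast-cancer-wisconsin.data)",
  "sep": ",",
  "header": false,
  "column_names": ["id", "clump_thickness", "uniformity_cell_size", "uniformity_cell_shape", "marginal_adhesion", "single_epithelial_cell_size", "bare_nuclei", "bland_chromatin", "normal_nucleoli", "mitoses", "class"],
  "label_column": "class",
  "positive_values": [2],
  "negative_values": [4],
  "drop_columns": ["id"],
  "missing_markers": ["?", ""]
}
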