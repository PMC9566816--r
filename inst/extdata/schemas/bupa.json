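{
  "dataset": "Bupa liver disorders (bupa.data)",
  "sep": ",",
  "header": false,
  "column_names": ["mcv", "alkphos", "sgpt", "sgot", "gammagt", "drinks", "selector"],
  "label_column": "selector",
  "positive_values": [1],
  "negative_values": [2],
  "drop_columns": [],
  "missing_markers": ["?", ""]
}
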