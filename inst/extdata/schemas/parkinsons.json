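{
  "dataset": "Parkinson (parkinsons.data)",
  "sep": ",",
  "header": true,
  "label_column": "status",
  "positive_values": [1],
  "negative_values": [0],
  "drop_columns": ["name"],
  "missing_markers": ["?", ""]
}
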