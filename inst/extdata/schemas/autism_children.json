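{
  "dataset": "Autistic Spectrum Disorder Screening Data for Children (CSV export of the ARFF)",
  "sep": ",",
  "header": true,
  "label_column": "Class_ASD",
  "positive_values": ["YES"],
  "negative_values": ["NO"],
  "drop_columns": [],
  "missing_markers": ["?", ""]
}
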