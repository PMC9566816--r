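{
  "dataset": "Cleveland heart disease (processed.cleveland.data); multi-grade label binarized 0 vs >0",
  "sep": ",",
  "header": false,
  "column_names": ["age", "sex", "chest_pain", "resting_bp", "cholesterol", "fasting_blood_sugar", "resting_ecg", "max_heart_rate", "exercise_angina", "oldpeak", "slope", "n_vessels", "thal", "num"],
  "label_column": "num",
  "positive_values": [1, 2, 3, 4],
  "negative_values": [0],
  "drop_columns": [],
  "missing_markers": ["?", ""]
}
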