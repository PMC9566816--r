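{
  "dataset": "Heart disease (Statlog, heart.dat)",
  "sep": " ",
  "header": false,
  "column_names": ["age", "sex", "chest_pain", "resting_bp", "cholesterol", "fasting_blood_sugar", "resting_ecg", "max_heart_rate", "exercise_angina", "oldpeak", "slope", "n_vessels", "thal", "class"],
  "label_column": "class",
  "positive_values": [1],
  "negative_values": [2],
  "drop_columns": [],
  "missing_markers": ["?", ""]
}
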