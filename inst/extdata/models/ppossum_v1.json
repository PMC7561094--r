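{
  "schema_version": 1,
  "name": "ppossum_v1",
  "link": "logit",
  "intercept": -9.065,
  "terms": [
    {"variable": "physiological_score", "level": null, "coefficient": 0.1692},
    {"variable": "operative_score", "level": null, "coefficient": 0.1550}
  ],
  "variable_map": {
    "physiological_score": "possum_physiology",
    "operative_score": "possum_operative"
  },
  "urgency_map": {"expedited": "elective"},
  "possum_bands": {
    "physiology": [
      {"name": "age", "source": "age_years", "type": "numeric", "bands": [
        {"hi": 60, "score": 1}, {"hi": 70, "score": 2}, {"score": 4}]},
      {"name": "cardiac", "source": "cardiac_signs", "type": "categorical",
        "scores": {"none": 1, "therapy": 2, "oedema": 4, "jvp": 8}},
      {"name": "respiratory", "source": "respiratory_signs", "type": "categorical",
        "scores": {"none": 1, "mild": 2, "moderate": 4, "severe": 8}},
      {"name": "systolic_bp", "source": "systolic_bp", "type": "numeric", "bands": [
        {"lo": 110, "hi": 130, "score": 1},
        {"lo": 131, "hi": 170, "score": 2}, {"lo": 100, "hi": 109, "score": 2},
        {"lo": 171, "score": 4}, {"lo": 90, "hi": 99, "score": 4},
        {"hi": 89, "score": 8}]},
      {"name": "pulse", "source": "pulse", "type": "numeric", "bands": [
        {"lo": 50, "hi": 80, "score": 1},
        {"lo": 81, "hi": 100, "score": 2}, {"lo": 40, "hi": 49, "score": 2},
        {"lo": 101, "hi": 120, "score": 4},
        {"lo": 121, "score": 8}, {"hi": 39, "score": 8}]},
      {"name": "gcs", "source": "gcs", "type": "numeric", "bands": [
        {"lo": 15, "score": 1}, {"lo": 12, "hi": 14, "score": 2},
        {"lo": 9, "hi": 11, "score": 4}, {"hi": 8, "score": 8}]},
      {"name": "haemoglobin", "source": "haemoglobin", "type": "numeric", "bands": [
        {"lo": 13, "hi": 16, "score": 1},
        {"lo": 11.5, "hi": 12.9, "score": 2}, {"lo": 16.1, "hi": 17, "score": 2},
        {"lo": 10, "hi": 11.4, "score": 4}, {"lo": 17.1, "hi": 18, "score": 4},
        {"hi": 9.9, "score": 8}, {"lo": 18.1, "score": 8}]},
      {"name": "wbc", "source": "wbc", "type": "numeric", "bands": [
        {"lo": 4, "hi": 10, "score": 1},
        {"lo": 10.1, "hi": 20, "score": 2}, {"lo": 3.1, "hi": 3.9, "score": 2},
        {"lo": 20.1, "score": 4}, {"hi": 3, "score": 4}]},
      {"name": "urea", "source": "urea", "type": "numeric", "bands": [
        {"hi": 7.5, "score": 1}, {"lo": 7.6, "hi": 10, "score": 2},
        {"lo": 10.1, "hi": 15, "score": 4}, {"lo": 15.1, "score": 8}]},
      {"name": "sodium", "source": "sodium", "type": "numeric", "bands": [
        {"lo": 136, "score": 1}, {"lo": 131, "hi": 135, "score": 2},
        {"lo": 126, "hi": 130, "score": 4}, {"hi": 125, "score": 8}]},
      {"name": "potassium", "source": "potassium", "type": "numeric", "bands": [
        {"lo": 3.5, "hi": 5, "score": 1},
        {"lo": 3.2, "hi": 3.4, "score": 2}, {"lo": 5.1, "hi": 5.3, "score": 2},
        {"lo": 2.9, "hi": 3.1, "score": 4}, {"lo": 5.4, "hi": 5.9, "score": 4},
        {"hi": 2.8, "score": 8}, {"lo": 6, "score": 8}]},
      {"name": "ecg", "source": "ecg", "type": "categorical",
        "scores": {"normal": 1, "af_60_90": 4, "other_abnormal": 8}}
    ],
    "operative": [
      {"name": "severity", "source": "severity", "type": "categorical",
        "scores": {"minor": 1, "intermediate": 2, "major": 4, "xmajor": 8, "complex": 8}},
      {"name": "procedures", "source": "procedure_count", "type": "categorical",
        "scores": {"1": 1, "2": 4, ">2": 8}},
      {"name": "blood_loss", "source": "blood_loss", "type": "categorical",
        "scores": {"<=100": 1, "101-500": 2, "501-999": 4, ">=1000": 8}},
      {"name": "soiling", "source": "soiling", "type": "categorical",
        "scores": {"none": 1, "serous": 2, "local_pus": 4, "free": 8}},
      {"name": "malignancy", "source": "malignancy", "type": "categorical",
        "scores": {"none": 1, "primary": 2, "nodal": 4, "metastatic": 8}},
      {"name": "mode", "source": "urgency", "type": "categorical",
        "scores": {"elective": 1, "expedited": 1, "urgent": 4, "immediate": 8}}
    ]
  },
  "provenance": "Portsmouth-POSSUM 30-day mortality equation (Prytherch et al., Br J Surg 1998;85:1217-20): logit = -9.065 + 0.1692 x physiological score + 0.1550 x operative severity score, with the classic POSSUM 12-item physiological and 6-item operative banding (each item 1/2/4/8). NCEPOD 'expedited' urgency mapped to the elective operative mode band. Cardiac and respiratory signs derived from the record's comorbidity flags (cardiac failure -> oedema band, coronary artery disease -> therapy band, COPD -> mild band). Coefficients and bands transcribed from the original publications; verify against the source before clinical use. v1"
}
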