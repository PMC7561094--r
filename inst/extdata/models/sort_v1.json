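{
  "schema_version": 1,
  "name": "sort_v1",
  "link": "logit",
  "intercept": -7.366,
  "terms": [
    {"variable": "asa_ps", "level": "3", "coefficient": 1.411},
    {"variable": "asa_ps", "level": "4", "coefficient": 2.388},
    {"variable": "asa_ps", "level": "5", "coefficient": 4.081},
    {"variable": "urgency", "level": "expedited", "coefficient": 0.712},
    {"variable": "urgency", "level": "urgent", "coefficient": 1.657},
    {"variable": "urgency", "level": "immediate", "coefficient": 2.452},
    {"variable": "highrisk_specialty", "level": "yes", "coefficient": 0.381},
    {"variable": "severity_band", "level": "yes", "coefficient": 0.667},
    {"variable": "malignancy", "level": "yes", "coefficient": 0.897},
    {"variable": "age_band", "level": "65-79", "coefficient": 0.777},
    {"variable": "age_band", "level": "80+", "coefficient": 1.591}
  ],
  "variable_map": {
    "asa_ps": "asa_class",
    "urgency": "urgency",
    "highrisk_specialty": "highrisk_specialty",
    "severity_band": "severity_xmajor_complex",
    "malignancy": "malignancy_any",
    "age_band": "age_band"
  },
  "provenance": "Surgical Outcome Risk Tool (SORT), 6-variable logistic model for 30-day postoperative mortality (Protopapa et al., Br J Surg 2014;101:1774-83). Reference levels: ASA-PS I-II, elective urgency, non-high-risk specialty, severity below Xmajor, no active malignancy, age 18-64. High-risk specialties: gastrointestinal, thoracic/cardiac, vascular. Coefficients transcribed from the original publication; verify against the source before clinical use. v1"
}
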