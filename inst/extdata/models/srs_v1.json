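{
  "schema_version": 1,
  "name": "srs_v1",
  "link": "logit",
  "intercept": -9.81,
  "terms": [
    {"variable": "srs_score", "level": null, "coefficient": 0.84}
  ],
  "variable_map": {
    "srs_score": "srs_score"
  },
  "srs_maps": {
    "cepod": {"elective": 1, "expedited": 2, "urgent": 3, "immediate": 4},
    "bupa": {"minor": 1, "intermediate": 2, "major": 3, "xmajor": 4, "complex": 5}
  },
  "provenance": "Surgical Risk Scale (SRS) (Sutton et al., Br J Surg 2002;89:763-8): mortality logit linear in the sum of CEPOD urgency class (1-4; NCEPOD 'expedited' mapped to the historical 'scheduled' class 2), BUPA procedure-severity grade (1-5) and ASA-PS (1-5). Coefficients transcribed from the original publication; verify against the source before clinical use. v1"
}
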