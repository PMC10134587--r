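{
  "table": "pretest",
  "description": "Published pretest decision-making competency counts per study arm, plus the age summary used for the baseline one-way ANOVA.",
  "groups": ["control", "cdv", "bade"],
  "n": [206, 203, 198],
  "counts": {
    "compliant": [144, 152, 142],
    "false_positive": [44, 47, 37],
    "false_negative": [104, 95, 106],
    "true_positive": [58, 61, 55]
  },
  "printed": {
    "percent": {
      "compliant": [69.90, 74.88, 71.72],
      "false_positive": [21.36, 23.15, 18.69],
      "false_negative": [50.49, 46.80, 53.54],
      "true_positive": [28.16, 30.05, 27.78]
    },
    "ppv": [0.57, 0.56, 0.60],
    "sensitivity": [0.36, 0.39, 0.34],
    "ppv_pooled": 0.58,
    "sensitivity_pooled": 0.36,
    "chi_square": {
      "compliant": 1.29,
      "false_positive": 1.22,
      "false_negative": 1.83,
      "true_positive": 0.29
    }
  },
  "age_summary": {
    "n": [206, 203, 198],
    "mean": [21.30, 21.59, 21.53],
    "sd": [1.44, 1.49, 2.00],
    "printed_f": 1.74
  }
}
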