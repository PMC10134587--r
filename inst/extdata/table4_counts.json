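{
  "table": "posttest",
  "description": "Published posttest decision-making competency counts per study arm.",
  "groups": ["control", "cdv", "bade"],
  "n": [206, 203, 198],
  "counts": {
    "compliant": [155, 191, 172],
    "false_positive": [37, 17, 24],
    "false_negative": [106, 60, 76],
    "true_positive": [63, 126, 98]
  },
  "printed": {
    "percent": {
      "compliant": [75.24, 94.09, 86.87],
      "false_positive": [17.96, 8.37, 12.12],
      "false_negative": [51.46, 29.56, 38.38],
      "true_positive": [30.58, 62.07, 49.49]
    },
    "ppv": [0.63, 0.88, 0.80],
    "sensitivity": [0.37, 0.68, 0.56],
    "chi_square": {
      "compliant": 29.57,
      "false_positive": 8.53,
      "false_negative": 20.72,
      "true_positive": 41.24
    }
  }
}
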