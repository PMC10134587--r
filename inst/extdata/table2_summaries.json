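{
  "table": "questionnaire_quality",
  "description": "Published posttest questionnaire summary statistics (selected quality dimensions) per study arm: group sizes, means, standard deviations, the printed one-way ANOVA F and the printed Scheffe ordering (arms labelled a = control, b = cdv, c = bade).",
  "groups": ["control", "cdv", "bade"],
  "n": [206, 203, 198],
  "rows": [
    {
      "dimension": "timeliness",
      "mean": [1.86, 3.06, 2.66],
      "sd": [1.31, 1.21, 1.25],
      "printed_f": 48.35,
      "printed_ordering": "a < c < b"
    },
    {
      "dimension": "perceived_ease_of_use",
      "mean": [1.03, 2.80, 2.47],
      "sd": [1.36, 1.27, 1.27],
      "printed_f": 107.64,
      "printed_ordering": "a < c < b"
    },
    {
      "dimension": "perceived_usefulness",
      "mean": [1.31, 3.03, 2.60],
      "sd": [1.35, 1.22, 1.23],
      "printed_f": 101.71,
      "printed_ordering": "a < c < b"
    },
    {
      "dimension": "completeness",
      "mean": [2.22, 3.04, 2.78],
      "sd": [1.40, 1.32, 1.26],
      "printed_f": 20.65,
      "printed_ordering": "a < b; a < c"
    }
  ]
}
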