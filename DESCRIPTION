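Package: kbcdss
Title: Knowledge-Based Clinical Decision Support for Psychiatric Nursing Diagnosis
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and evaluates knowledge-based clinical decision support
    for psychiatric nursing care planning. Indicator tables linking nursing
    assessment items to the defining characteristics, related factors and
    risk factors of a standardized diagnosis taxonomy are scored either with
    the Clinical Diagnostic Validity (CDV) weighted interrater reliability
    ratio of Fehring or with a Bayesian posterior computed from patient
    co-occurrence registries. Scored indicators are turned into ranked
    per-diagnosis guidance for a patient's positive assessment findings.
    The package also implements the evaluation of diagnostic decision-making
    competency (per-participant true/false positive and false negative
    classification against an expert reference, positive predictive value,
    sensitivity, and the at-least-three-defining-characteristics compliance
    rule), the accompanying group-comparison statistics (Pearson chi-square,
    McNemar-Bowker symmetry test, one-way ANOVA from summary statistics,
    single-covariate ANCOVA, Scheffe post hoc comparisons, and
    noncentral-F power and sample-size calculation), and a seeded synthetic
    generator for knowledge bases, dual-rater observation streams,
    co-occurrence registries and three-arm pre/post study cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    car,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
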