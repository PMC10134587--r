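---
title: "Models and methods behind kbcdss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind kbcdss}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kbcdss)
```

This vignette is the package's own account of its models, the choices made
where the underlying procedures were open to interpretation, and what the
synthetic-data generator does and does not establish.

## The knowledge base

A `knowledge_base` holds a diagnosis taxonomy — each diagnosis either
*actual* (carrying defining characteristics and optionally related factors)
or *risk*-type (carrying risk factors) — together with assessment items
organised in five aspects of a holistic psychiatric nursing assessment
(physical, psychological, social, developmental, spiritual), candidate
item–element associations, and optionally a scored indicator table.
Validation enforces that every actual diagnosis offers at least three
defining characteristics (and every risk diagnosis three risk factors), so
the compliance rule below is satisfiable for every diagnosis; a base
violating this is rejected at construction and reported by
`validate_knowledge_base()` as *compliance rule unsatisfiable*.

Identifiers are case-sensitive exact-match strings: locale-dependent case
folding has no place in a clinical vocabulary. Out-of-taxonomy element ids
in care plans are **retained and flagged invalid** rather than rejected,
because the competency evaluation must see them as evidence of
over-identification; silently dropping them would bias the false-positive
side of the evaluation downward.

## The CDV engine

The weighted interrater reliability ratio for one association observed on
$N$ patients by a junior ($F_1$ positives) and a senior nurse
($F_2$ positives), with $A$ agreements and $D = N - A$ disagreements, is

$$R = \frac{F_1/N + F_2/N}{2}\cdot\frac{A}{A+D}.$$

$R \ge 0.80$ is a *major* indicator, $0.50 \le R < 0.80$ *minor*, below
$0.50$ *excluded*. Both thresholds are inclusive at their lower edge, so
$R = 0.80$ is major and $R = 0.50$ is minor. Excluded entries stay in the
table (marked non-displayable): a knowledge-base build is then a complete,
reproducible record even though the guidance screen shows only major and
minor indicators.

Two conventions were genuinely open:

* **What counts as agreement.** The default (`agreement_mode =
  "both_states"`) counts a patient as an agreement when the two raters'
  presence/absence judgments coincide — the usual interrater-reliability
  convention. The alternative reading, agreement only on joint presence, is
  available as `"presence_only"`.
* **What N is.** $N$ is the number of patients observed *for that
  association* (per-association), not the global patient count; an
  association unassessable for some patients is then not penalised. Callers
  who want a global $N$ can pad the observation stream explicitly.

A useful consequence of the per-patient definition, exploited in the test
suite: $F_1 + F_2 = 2\,(\text{both present}) + D$, so $F_1 + F_2$ and $D$
always share parity. Tally quintuples violating this (such as
$F_1=8, F_2=9, A=8, D=2$) cannot arise from data, although the formula
itself is still defined for them.

## The Bayesian engine

For one association the engine scores the posterior probability of the
element given a positive finding,

$$P(DC\,|\,+) = \frac{P(+|DC)\,P(DC)}
{P(+|DC)\,P(DC) + P(+|Non\_DC)\,P(Non\_DC)},$$

with the three probabilities estimated from a patient co-occurrence
registry by relative frequency. Two choices:

* **Estimation.** No estimation procedure is prescribed by the model
  itself; plain relative frequency matches the marginal-probability reading
  literally, with an explicit error on an empty margin. An optional
  symmetric pseudo-count `smoothing = s` (add $s$ to each conditional cell,
  $2s$ to its denominator) makes degenerate registries usable; the default
  is $s = 0$ so that degeneracy is loud, not silent.
* **Display thresholds.** The Bayesian guidance reuses the CDV bands
  (0.80/0.50) by default so the two study arms see comparably sparse
  guidance; both the raw posterior and the thresholded level are emitted,
  since which of the two the original screen showed is not documented.

All three association families (assessment → defining characteristic,
defining characteristic → related factor, assessment → risk factor) share
one registry schema and one code path, distinguished only by the element
type resolved in the knowledge base.

## Guidance

`generate_guidance()` is a pure function of (findings, indicator table,
knowledge base). Within a diagnosis, elements reachable from several
positive findings are deduplicated keeping the **maximum** score (guidance
shows the strongest evidence), and diagnoses are ranked by

1. number of distinct major elements (descending),
2. sum of scores (descending),
3. diagnosis code (lexicographic).

No ordering is prescribed by the underlying screen design; majors-first
mirrors the role of the major level as the primary assessment criterion,
and the lexicographic tail makes the output deterministic, which the
byte-identity property test relies on. The control arm is emulated by
`null_guidance()`: taxonomy-ordered element lists with no scores and no
ranking, i.e. a care planning system without guidance indicators.

## Competency evaluation

`classify_cohort()` pairs each student plan with the researcher's reference
for the same (participant, patient, phase, diagnosis) and compares **counts
of taxonomy-valid elements**: equal → TP, more → FP, fewer → FN. The
count comparison (rather than set identity) is the default because it is
the arithmetic that reproduces published competency tables; a stricter
`mode = "set"` is available, under which equal-count-different-content
pairs fall to the FP side when the student cited at least as many valid
elements. Out-of-taxonomy elements are excluded from the count on *both*
sides. Compliance is `adequately_supported()`: at least three distinct
taxonomy-valid elements (defining characteristics, or risk factors for
risk diagnoses); related factors never count toward the rule.

One evaluated care plan per participant per phase is assumed and enforced
(`aggregate_competency()` errors on duplicates): the TP/FP/FN classes then
partition each group, which is the invariant that makes per-group counts,
PPV and sensitivity well defined.

Displayed proportions and percentages use **half-up rounding to two
decimals** (`round_half_up()`), matching how clinical tables are printed;
base R's round-half-to-even would print 0.875 as 0.87. Internally all
scores are kept at full precision.

## The statistics battery

* **Pearson chi-square** (`pearson_chi_square()`): $\sum (O-E)^2/E$,
  margins-based expectations, **no continuity correction** anywhere — the
  published 2×3 statistics reproduce only without it. Zero expected cells
  are an error, not an NA.
* **McNemar–Bowker** (`mcnemar_bowker()`): Bowker's statistic over
  discordant pairs; a pair with both off-diagonal cells zero contributes
  nothing and drops one df; a table with *no* discordant pairs is reported
  as undefined (statistic `NA` with a note) rather than 0, since the test
  statistic is then 0/0.
* **Summary ANOVA** (`anova_from_summary()`): between- and within-group
  sums of squares reconstructed from (n, mean, SD); identical to raw-data
  ANOVA when the summaries are exact (a property test asserts this).
  Zero within-variance with non-zero between-variance yields an infinite
  statistic with p = 0.
* **ANCOVA** (`ancova_one_covariate()`): least squares via `lm`, group
  effect tested by model comparison against the covariate-only model —
  Type III sums of squares under sum-to-zero coding, the standard choice
  for unbalanced groups; df $(k-1,\,N-k-1)$.
* **Scheffé** (`scheffe_posthoc()`): pair $(i,j)$ significant iff
  $(m_i-m_j)^2 / (\mathrm{MSW}(1/n_i+1/n_j)) > (k-1)F_{\alpha;k-1,N-k}$.
  The ordering string encodes a full chain (`"a < c < b"`) when every pair
  separates and a `;`-joined list of significant pairs otherwise, with
  groups labelled `a`, `b`, `c` in input order.
* **Power and sample size** (`ancova_power()`,
  `ancova_sample_size()`): noncentral-F power with $\lambda = f^2 N$ and
  denominator df $N - k - c$; the sample-size search doubles an upper
  bound and bisects (the power function is monotone in $N$, which a test
  asserts). Under this convention the canonical design input
  $(f=0.2,\ \alpha=0.05,\ \text{power}=0.99,\ k=3,\ c=1)$ yields
  $N = 538$, i.e. 180 per group, and 15% dropout inflation gives 212 per
  group (636 total). Conventions differ across software in whether
  $\lambda$ uses the total or the effective N and in the denominator df;
  this package documents and tests exactly the convention above.
* **p-values** come from distribution tails, never lookup tables, and print
  as three decimals with `"< .001"` below that.

### Tolerances for recomputed F statistics

`run_study_reproduction()` recomputes ANOVA F values from printed
two-decimal (n, mean, SD) summaries. Rounding the group means to two
decimals perturbs the small between-group differences enough to move the
recomputed F by up to about 1.5% for the questionnaire dimensions (whose
mean differences are of order 0.3–1.8 on an 11-point scale), so the report
compares questionnaire F values within 2% and the baseline age F — whose
larger relative mean spread makes it far less sensitive — within 0.5%.
Proportions, percentages and chi-squares recomputed from integer counts
are exact and compared at two decimals.

## The synthetic generator

`simulation_config()` fixes the study conditions; every generator is a
deterministic function of the seed (distinct sub-seeds per generator keep
the knowledge-base, rater, registry and cohort streams independent).

**What it emulates, and the defaults.**

* A 22-diagnosis knowledge base (roughly one fifth risk-type) with 6
  defining characteristics or risk factors per diagnosis, 25 assessment
  items over the five aspects, one candidate association per element.
* Dual raters: per patient and association a latent truth with prevalence
  0.7; each rater reports the truth with probability `rater_agreement`
  (default 0.9), flipped otherwise, independently. Under this model each
  rater's positive rate is $p = \pi a + (1-\pi)(1-a)$ and the expected
  agreement rate $a^2 + (1-a)^2$, so the mean weighted ratio concentrates
  near $p\,(a^2+(1-a)^2)$ — the closed form the property tests assert.
* Registry: element present with prevalence 0.7; finding positive with
  sensitivity 0.85 given presence and false-alarm rate 0.10 otherwise.
* Cohort: arm sizes 206/203/198, one evaluated diagnosis per participant
  per phase. The researcher's plan is the latent truth (each taxonomy
  element present with prevalence 0.7, hence about 4.2 reference elements
  per plan); the student keeps each true element with the arm- and
  phase-specific *fidelity* and adds each absent taxonomy element at the
  *over-identification* rate. Pretest behaviour is arm-identical
  (fidelity 0.75, over-identification 0.15 — producing pretest true
  positive rates around 30% and compliance around 75%, the regime of an
  unguided cohort); posttest fidelities 0.95/0.88/0.75 and
  over-identification 0.04/0.08/0.15 for CDV/BADE/control encode the
  guided-arm advantage as an identification-fidelity shift.

**What it does not emulate.** The generator's purpose is to exercise the
evaluator and the statistics, not to model cognition: there is no model of
*why* guidance improves identification, no heterogeneity of prevalence or
difficulty across diagnoses or elements, no questionnaire responses, no
participant-level covariates, and no dropout. Consequently, passing tests
show that the pipeline is correct and calibrated under its own stated
noise model — they do not validate the behavioural claim that guidance
causes the fidelity shift, nor the magnitudes of real-world PPV or
sensitivity values.

**Calibration.** With arm-identical parameters the whole
simulate–classify–test pipeline is a null model: the between-arm chi-square
rejects at about the nominal 5%. The acceptance script and test suite
check this, along with fidelity recovery (the empirical identification
rate recovers the configured fidelity within ±0.03 at 200 participants per
arm, a 4-standard-error band) and the Monte-Carlo posttest ordering
CDV > BADE > control in expectation.

## Problem sizes and runtime choices

The shipped checks use: exhaustive rater-pattern enumeration up to
$N = 4$ (all $2^N \times 2^N$ patterns); 2000 replicates for the null
calibration of the chi-square and ANCOVA tests (binomial standard error
0.005 against the ±0.02 acceptance band); 200 replicate cohorts of about
200 participants for the ordering check; and 200 participants per arm for
fidelity recovery. These sizes put every Monte-Carlo standard error at a
quarter or less of the band it is tested against while keeping the whole
suite in tens of seconds.

## Known limitations

* The CDV model is defined for exactly one junior/senior rater pair; there
  is no generalisation to more raters.
* The Bayesian engine scores associations independently; no joint
  (naive-Bayes) combination across assessment items is attempted.
* Specificity and negative predictive value are undefined in this
  evaluation scheme (there are no true negatives), and within-group
  McNemar tests on published tables require paired discordant counts that
  summary tables do not carry — `mcnemar_bowker()` is therefore exercised
  on synthetic and constructed tables only.
* ANCOVA F values for published PPV/sensitivity comparisons cannot be
  recomputed from group-level summaries (they require per-subject pre/post
  scores); the ANCOVA routine is instead validated against a
  general-purpose least-squares oracle and by null calibration and power
  checks on synthetic data.
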