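test_that("the mock knowledge base matches the configured shape and is valid", {
  cfg <- simulation_config(seed = 1)
  kb <- generate_mock_kb(cfg)
  expect_equal(length(kb$diagnoses), 22L)
  expect_setequal(unique(kb$assessment_items$aspect), KB_ASPECTS)
  expect_length(validate_knowledge_base(kb), 0L)
  # every diagnosis supports the compliance rule
  for (d in kb$diagnoses) {
    key <- if (d$dx_type == "risk") "risk_factor" else "defining_characteristic"
    expect_gte(sum(d$elements$element_type == key), 3L)
  }
  expect_error(simulation_config(n_elements_per_diagnosis = 2),
               "compliance rule unsatisfiable")
})

test_that("all generators are deterministic under a fixed seed", {
  cfg <- simulation_config(seed = 17)
  kb1 <- generate_mock_kb(cfg)
  kb2 <- generate_mock_kb(cfg)
  expect_identical(serialize(kb1, NULL), serialize(kb2, NULL))
  expect_identical(simulate_rater_observations(kb1, cfg),
                   simulate_rater_observations(kb2, cfg))
  expect_identical(simulate_registry(kb1, cfg),
                   simulate_registry(kb2, cfg))
  expect_identical(simulate_cohort(kb1, cfg), simulate_cohort(kb2, cfg))
  # and a different seed changes the stream
  cfg2 <- simulation_config(seed = 18)
  expect_false(identical(simulate_cohort(kb1, cfg),
                         simulate_cohort(kb1, cfg2)))
})

test_that("perfectly agreeing raters yield zero disagreement everywhere", {
  cfg <- simulation_config(seed = 2, rater_agreement = 1, n_patients = 8)
  kb <- generate_mock_kb(cfg)
  tal <- tally_rater_agreement(simulate_rater_observations(kb, cfg))
  expect_true(all(tal$A == tal$N))
  expect_true(all(tal$D == 0))
})

test_that("mean weighted ratio follows the noise-model closed form", {
  # per-rater positive rate p = prev*a + (1-prev)*(1-a); agreement rate
  # a^2 + (1-a)^2; E[R] is approximately their product at large N
  for (a in c(0.5, 0.9)) {
    cfg <- simulation_config(seed = 31, rater_agreement = a,
                             prevalence = 0.7, n_patients = 150)
    kb <- generate_mock_kb(cfg)
    tal <- tally_rater_agreement(simulate_rater_observations(kb, cfg))
    r <- cdv_weighted_ratio(tal$F1, tal$F2, tal$N, tal$A, tal$D)
    p <- 0.7 * a + 0.3 * (1 - a)
    expected <- p * (a^2 + (1 - a)^2)
    expect_equal(mean(r), expected, tolerance = 0.02)
  }
})

test_that("simulated registries recover the generating probabilities", {
  cfg <- simulation_config(seed = 4, n_patients = 400)
  kb <- generate_mock_kb(cfg)
  reg <- simulate_registry(kb, cfg)
  p <- estimate_probabilities(sum(reg$n_pos_dc), sum(reg$n_neg_dc),
                              sum(reg$n_pos_nondc), sum(reg$n_neg_nondc))
  expect_equal(p$p_dc, cfg$prevalence, tolerance = 0.02)
  expect_equal(p$p_pos_given_dc, cfg$finding_sensitivity, tolerance = 0.02)
  expect_equal(p$p_pos_given_nondc, cfg$finding_false_alarm,
               tolerance = 0.02)
})

test_that("a perfect-fidelity cohort is entirely true positive", {
  ones <- c(control = 1, cdv = 1, bade = 1)
  zeros <- c(control = 0, cdv = 0, bade = 0)
  cfg <- simulation_config(
    seed = 5, arm_sizes = c(control = 20, cdv = 20, bade = 20),
    fidelity = list(pretest = ones, posttest = ones),
    overidentification = list(pretest = zeros, posttest = zeros))
  kb <- generate_mock_kb(cfg)
  tab <- aggregate_competency(classify_cohort(simulate_cohort(kb, cfg), kb))
  expect_true(all(tab$tp == tab$n))
  expect_true(all(tab$ppv == 1))
  expect_true(all(tab$sensitivity == 1))
})

test_that("simulated cohorts always satisfy the TP+FP+FN partition", {
  for (s in 1:3) {
    cfg <- simulation_config(seed = s, arm_sizes = c(control = 30, cdv = 25,
                                                     bade = 20))
    kb <- generate_mock_kb(cfg)
    tab <- aggregate_competency(classify_cohort(simulate_cohort(kb, cfg),
                                                kb))
    expect_true(all(tab$tp + tab$fp + tab$fn == tab$n))
    expect_equal(tab$n[tab$phase == "posttest"][order(match(
      tab$group[tab$phase == "posttest"], c("control", "cdv", "bade")))],
      c(30L, 25L, 20L))
  }
})

test_that("write_simulation emits a loadable, consistent artifact set", {
  out <- withr::local_tempdir()
  cfg <- simulation_config(seed = 6, arm_sizes = c(control = 8, cdv = 8,
                                                   bade = 8), n_patients = 6)
  res <- write_simulation(cfg, out)
  kb <- load_knowledge_base(file.path(out, "kb.json"))
  expect_length(validate_knowledge_base(kb), 0L)
  plans <- read_care_plans(file.path(out, "plans.csv"), kb)
  expect_equal(nrow(plans), 8L * 3L * 4L)
  obs <- read_rater_observations(file.path(out, "observations.csv"))
  expect_equal(nrow(obs), nrow(kb$associations) * cfg$n_patients)
  reg <- read_registry(file.path(out, "registry.csv"))
  expect_true(all(reg$n_pos_dc + reg$n_neg_dc + reg$n_pos_nondc +
                    reg$n_neg_nondc == cfg$n_patients))
  manifest <- jsonlite::fromJSON(file.path(out, "manifest.json"))
  expect_equal(manifest$seed, 6L)
})
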