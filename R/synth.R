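# Seeded synthetic-data generator: mock knowledge bases, paired-rater
# observation streams, patient co-occurrence registries, and three-arm
# pre/post study cohorts. Everything is deterministic given the config seed.

#' Simulation configuration
#'
#' Bundles and validates every tunable of the synthetic generator. The
#' defaults emulate the study conditions: a 22-diagnosis knowledge base over
#' the 5-aspect assessment framework, arm sizes 206 (control), 203 (CDV) and
#' 198 (BADE), arm-identical pretest behaviour, and posttest identification
#' fidelity ordered CDV > BADE > control.
#'
#' @param seed integer RNG seed; every generator output is a deterministic
#'   function of the config (functions derive distinct sub-seeds internally,
#'   so the knowledge base, observation, registry and cohort streams are
#'   independent).
#' @param n_diagnoses number of diagnoses (default 22).
#' @param n_items_per_aspect assessment items per aspect (5 aspects, fixed).
#' @param n_elements_per_diagnosis defining characteristics (or risk
#'   factors) per diagnosis; must be >= 3 so the compliance rule is
#'   satisfiable.
#' @param risk_fraction fraction of risk-type diagnoses.
#' @param n_patients patients in the rater-observation and registry streams.
#' @param rater_agreement probability that a rater reports the latent truth
#'   of an association (applied independently to each rater).
#' @param prevalence probability that an element is truly present for a
#'   patient.
#' @param finding_sensitivity registry probability of a positive assessment
#'   finding when the element is present.
#' @param finding_false_alarm registry probability of a positive finding
#'   when the element is absent.
#' @param arm_sizes named integer vector (control, cdv, bade).
#' @param fidelity named list with `pretest` and `posttest`, each a named
#'   probability vector per arm: chance a student identifies a truly present
#'   element.
#' @param overidentification same shape: chance a student adds a taxonomy
#'   element the researcher did not identify.
#' @return validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_diagnoses = 22L,
                              n_items_per_aspect = 5L,
                              n_elements_per_diagnosis = 6L,
                              risk_fraction = 0.2,
                              n_patients = 40L,
                              rater_agreement = 0.9,
                              prevalence = 0.7,
                              finding_sensitivity = 0.85,
                              finding_false_alarm = 0.10,
                              arm_sizes = c(control = 206L, cdv = 203L,
                                            bade = 198L),
                              fidelity = list(
                                pretest = c(control = 0.75, cdv = 0.75,
                                            bade = 0.75),
                                posttest = c(control = 0.75, cdv = 0.95,
                                             bade = 0.88)),
                              overidentification = list(
                                pretest = c(control = 0.15, cdv = 0.15,
                                            bade = 0.15),
                                posttest = c(control = 0.15, cdv = 0.04,
                                             bade = 0.08))) {
  cfg <- list(seed = as.integer(seed), n_diagnoses = as.integer(n_diagnoses),
              n_aspects = 5L,
              n_items_per_aspect = as.integer(n_items_per_aspect),
              n_elements_per_diagnosis = as.integer(n_elements_per_diagnosis),
              risk_fraction = risk_fraction, n_patients = as.integer(n_patients),
              rater_agreement = rater_agreement, prevalence = prevalence,
              finding_sensitivity = finding_sensitivity,
              finding_false_alarm = finding_false_alarm,
              arm_sizes = arm_sizes, fidelity = fidelity,
              overidentification = overidentification)
  for (f in c("n_diagnoses", "n_items_per_aspect", "n_patients")) {
    assert_that(cfg[[f]] >= 1L, sprintf("'%s' must be >= 1", f))
  }
  assert_that(cfg$n_elements_per_diagnosis >= 3L,
              "n_elements_per_diagnosis must be >= 3 (compliance rule unsatisfiable otherwise)")
  for (f in c("risk_fraction", "rater_agreement", "prevalence",
              "finding_sensitivity", "finding_false_alarm")) {
    check_prob(cfg[[f]], f)
  }
  assert_that(all(GROUPS %in% names(cfg$arm_sizes)),
              "arm_sizes must name control, cdv and bade")
  assert_that(all(cfg$arm_sizes >= 1), "arm sizes must be >= 1")
  for (ph in PHASES) {
    for (f in c("fidelity", "overidentification")) {
      assert_that(all(GROUPS %in% names(cfg[[f]][[ph]])),
                  sprintf("%s$%s must name every arm", f, ph))
      check_prob(cfg[[f]][[ph]], sprintf("%s$%s", f, ph))
    }
  }
  class(cfg) <- "simulation_config"
  cfg
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf("Simulation config (seed %d)\n", x$seed))
  cat(sprintf("  knowledge base: %d diagnoses x %d elements, %d x %d items\n",
              x$n_diagnoses, x$n_elements_per_diagnosis, x$n_aspects,
              x$n_items_per_aspect))
  cat(sprintf("  raters: %d patients, agreement %.2f, prevalence %.2f\n",
              x$n_patients, x$rater_agreement, x$prevalence))
  cat(sprintf("  arms: %s\n",
              paste(sprintf("%s=%d", names(x$arm_sizes), x$arm_sizes),
                    collapse = ", ")))
  invisible(x)
}

# derive a reproducible sub-seed per generator so streams are independent;
# double arithmetic avoids 32-bit overflow for large user seeds
sub_seed <- function(cfg, offset) {
  as.integer((as.numeric(cfg$seed) * 8 + offset) %% .Machine$integer.max)
}

#' Generate a mock knowledge base
#'
#' Builds a fully synthetic diagnosis taxonomy (neutral `DX-001` ... codes
#' and mock labels; no copyrighted taxonomy content) with assessment items
#' spread over the five framework aspects and one candidate item association
#' per element. Deterministic given the config seed.
#'
#' @param config a [simulation_config()].
#' @return a validated `knowledge_base` with `associations` filled in.
#' @export
generate_mock_kb <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(sub_seed(config, 0L))
  aspects <- rep(KB_ASPECTS, each = config$n_items_per_aspect)
  n_items <- length(aspects)
  items <- data.frame(
    item_id = sprintf("I-%03d", seq_len(n_items)),
    aspect = aspects,
    label = sprintf("mock %s assessment item %d", aspects,
                    sequence(rep(config$n_items_per_aspect, 5))),
    stringsAsFactors = FALSE)

  n_risk <- round(config$risk_fraction * config$n_diagnoses)
  is_risk <- seq_len(config$n_diagnoses) > (config$n_diagnoses - n_risk)
  diagnoses <- lapply(seq_len(config$n_diagnoses), function(i) {
    code <- sprintf("DX-%03d", i)
    risk <- is_risk[i]
    n_el <- config$n_elements_per_diagnosis
    if (risk) {
      el <- data.frame(
        element_id = sprintf("%s-RK%02d", code, seq_len(n_el)),
        element_type = "risk_factor",
        label = sprintf("mock risk factor %d of %s", seq_len(n_el), code),
        stringsAsFactors = FALSE)
    } else {
      el <- data.frame(
        element_id = c(sprintf("%s-DC%02d", code, seq_len(n_el)),
                       sprintf("%s-RF%02d", code, 1:2)),
        element_type = c(rep("defining_characteristic", n_el),
                         rep("related_factor", 2)),
        label = c(sprintf("mock defining characteristic %d of %s",
                          seq_len(n_el), code),
                  sprintf("mock related factor %d of %s", 1:2, code)),
        stringsAsFactors = FALSE)
    }
    list(dx_code = code,
         label = sprintf("mock %s diagnosis %02d",
                         if (risk) "risk" else "actual", i),
         dx_type = if (risk) "risk" else "actual",
         elements = el)
  })

  associations <- do.call(rbind, lapply(diagnoses, function(d) {
    data.frame(item_id = sample(items$item_id, nrow(d$elements),
                                replace = TRUE),
               dx_code = d$dx_code,
               element_id = d$elements$element_id,
               stringsAsFactors = FALSE)
  }))

  knowledge_base(diagnoses, items, associations = associations,
                 meta = list(engine = "mock",
                             seed = config$seed,
                             n_diagnoses = config$n_diagnoses,
                             n_elements_per_diagnosis =
                               config$n_elements_per_diagnosis))
}

#' Simulate a paired-rater observation stream
#'
#' For each patient and candidate association, a latent truth is drawn with
#' probability `prevalence`; each rater then reports the truth with
#' probability `rater_agreement` and its negation otherwise, independently
#' of the other rater.
#'
#' @param kb a `knowledge_base` with candidate `associations`.
#' @param config a [simulation_config()].
#' @return data frame of observations suitable for
#'   [tally_rater_agreement()].
#' @export
simulate_rater_observations <- function(kb, config = simulation_config()) {
  stopifnot(inherits(kb, "knowledge_base"))
  assert_that(!is.null(kb$associations), "knowledge base has no associations")
  set.seed(sub_seed(config, 1L))
  assoc <- kb$associations
  n_a <- nrow(assoc)
  n_p <- config$n_patients
  idx <- rep(seq_len(n_a), each = n_p)
  truth <- stats::runif(n_a * n_p) < config$prevalence
  report <- function(truth) {
    faithful <- stats::runif(length(truth)) < config$rater_agreement
    ifelse(faithful, truth, !truth)
  }
  data.frame(patient_id = rep(sprintf("P-%04d", seq_len(n_p)), times = n_a),
             item_id = assoc$item_id[idx],
             dx_code = assoc$dx_code[idx],
             element_id = assoc$element_id[idx],
             junior_present = as.integer(report(truth)),
             senior_present = as.integer(report(truth)),
             stringsAsFactors = FALSE)
}

#' Simulate a patient co-occurrence registry
#'
#' For each candidate association, `n_patients` patients are drawn: the
#' element is present with probability `prevalence`, and the assessment
#' finding is positive with probability `finding_sensitivity` when present
#' and `finding_false_alarm` when absent. Returns the four-cell counts per
#' association.
#'
#' @inheritParams simulate_rater_observations
#' @return registry data frame suitable for [build_bayes_indicators()].
#' @export
simulate_registry <- function(kb, config = simulation_config()) {
  stopifnot(inherits(kb, "knowledge_base"))
  assert_that(!is.null(kb$associations), "knowledge base has no associations")
  set.seed(sub_seed(config, 2L))
  assoc <- kb$associations
  n_a <- nrow(assoc)
  n <- config$n_patients
  n_dc <- stats::rbinom(n_a, n, config$prevalence)
  n_pos_dc <- stats::rbinom(n_a, n_dc, config$finding_sensitivity)
  n_pos_nondc <- stats::rbinom(n_a, n - n_dc, config$finding_false_alarm)
  data.frame(item_id = assoc$item_id, dx_code = assoc$dx_code,
             element_id = assoc$element_id,
             n_pos_dc = n_pos_dc,
             n_neg_dc = n_dc - n_pos_dc,
             n_pos_nondc = n_pos_nondc,
             n_neg_nondc = (n - n_dc) - n_pos_nondc,
             stringsAsFactors = FALSE)
}

#' Simulate a three-arm pre/post study cohort
#'
#' One evaluated diagnosis per participant per phase. The researcher's plan
#' is the latent truth (each taxonomy element present with probability
#' `prevalence`, restricted to defining characteristics for actual and risk
#' factors for risk diagnoses). The student keeps each truly present element
#' with the arm- and phase-specific fidelity and adds each absent taxonomy
#' element with the arm- and phase-specific over-identification rate.
#'
#' @inheritParams simulate_rater_observations
#' @return a care-plan data frame (class `care_plans`) with student and
#'   researcher records for both phases and all arms.
#' @export
simulate_cohort <- function(kb, config = simulation_config()) {
  stopifnot(inherits(kb, "knowledge_base"))
  set.seed(sub_seed(config, 3L))
  codes <- vapply(kb$diagnoses, `[[`, character(1), "dx_code")
  key_sets <- lapply(codes, function(code) kb_key_elements(kb, code))
  names(key_sets) <- codes
  n_key <- lengths(key_sets)

  rows <- vector("list", 4L * sum(config$arm_sizes))
  r <- 0L
  patient_no <- 0L
  for (arm in GROUPS) {
    n_arm <- config$arm_sizes[[arm]]
    pids <- sprintf("S-%s-%04d", arm, seq_len(n_arm))
    for (phase in PHASES) {
      fid <- config$fidelity[[phase]][[arm]]
      over <- config$overidentification[[phase]][[arm]]
      dx <- sample(codes, n_arm, replace = TRUE)
      for (i in seq_len(n_arm)) {
        patient_no <- patient_no + 1L
        ks <- key_sets[[dx[i]]]
        truth <- ks[stats::runif(n_key[[dx[i]]]) < config$prevalence]
        absent <- setdiff(ks, truth)
        kept <- truth[stats::runif(length(truth)) < fid]
        added <- absent[stats::runif(length(absent)) < over]
        pat <- sprintf("P-%05d", patient_no)
        r <- r + 1L
        rows[[r]] <- list(pids[i], pat, arm, phase, "researcher", dx[i],
                          truth)
        r <- r + 1L
        rows[[r]] <- list(pids[i], pat, arm, phase, "student", dx[i],
                          c(kept, added))
      }
    }
  }
  out <- data.frame(
    participant_id = vapply(rows, `[[`, character(1), 1L),
    patient_id = vapply(rows, `[[`, character(1), 2L),
    group = vapply(rows, `[[`, character(1), 3L),
    phase = vapply(rows, `[[`, character(1), 4L),
    role = vapply(rows, `[[`, character(1), 5L),
    dx_code = vapply(rows, `[[`, character(1), 6L),
    stringsAsFactors = FALSE)
  out$identified_elements <- lapply(rows, `[[`, 7L)
  out$invalid_elements <- rep(list(character()), nrow(out))
  class(out) <- c("care_plans", "data.frame")
  out
}

#' Run a full simulation and write its artifacts
#'
#' Writes `kb.json`, `observations.csv`, `registry.csv`, `plans.csv` and a
#' `manifest.json` recording the seed and config to `out_dir`.
#'
#' @param config a [simulation_config()].
#' @param out_dir output directory (created if missing).
#' @return invisibly, a list with the generated objects and file paths.
#' @export
write_simulation <- function(config, out_dir) {
  stopifnot(inherits(config, "simulation_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  kb <- generate_mock_kb(config)
  obs <- simulate_rater_observations(kb, config)
  reg <- simulate_registry(kb, config)
  plans <- simulate_cohort(kb, config)
  paths <- list(kb = file.path(out_dir, "kb.json"),
                observations = file.path(out_dir, "observations.csv"),
                registry = file.path(out_dir, "registry.csv"),
                plans = file.path(out_dir, "plans.csv"),
                manifest = file.path(out_dir, "manifest.json"))
  write_knowledge_base(kb, paths$kb)
  utils::write.csv(obs, paths$observations, row.names = FALSE, quote = FALSE)
  utils::write.csv(reg, paths$registry, row.names = FALSE, quote = FALSE)
  write_care_plans(plans, paths$plans)
  manifest <- list(command = "simulate", seed = config$seed,
                   config = unclass(config),
                   outputs = lapply(paths, basename),
                   timestamp = format(Sys.time(), tz = "UTC"))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), paths$manifest)
  invisible(list(kb = kb, observations = obs, registry = reg, plans = plans,
                 paths = paths))
}
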