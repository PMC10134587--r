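# Decision-making competency evaluation: per-participant TP/FP/FN
# classification against the researcher's reference plan, compliance with
# the >= 3-element rule, and per-group PPV / sensitivity aggregation.

#' Classify one student plan against the researcher's reference
#'
#' Counts the taxonomy-valid elements each of the two paired plans cites
#' (defining characteristics for actual diagnoses, risk factors for risk
#' diagnoses; out-of-taxonomy elements are excluded on both sides) and
#' classifies the participant by three-way comparison: equal counts is a
#' true positive, more than the researcher a false positive, fewer a false
#' negative. `mode = "set"` instead requires set identity of the valid
#' elements for a true positive (ties on count but not content fall to the
#' false-positive side when the student cited at least as many).
#'
#' @param student one-row care-plan data frame (role `student`).
#' @param researcher one-row care-plan data frame (role `researcher`), same
#'   participant, patient, phase and diagnosis.
#' @param kb a `knowledge_base`.
#' @param mode `"count"` (default; reproduces the published arithmetic) or
#'   `"set"`.
#' @return one-row data frame: `participant_id`, `group`, `phase`,
#'   `outcome` (`TP`/`FP`/`FN`), `compliant`, `n_student_valid`,
#'   `n_researcher_valid`.
#' @export
classify_participant <- function(student, researcher, kb,
                                 mode = c("count", "set")) {
  mode <- match.arg(mode)
  stopifnot(inherits(kb, "knowledge_base"))
  for (col in c("participant_id", "patient_id", "phase", "dx_code")) {
    if (!identical(student[[col]][[1]], researcher[[col]][[1]])) {
      stop(sprintf("student/researcher records disagree on %s ('%s' vs '%s')",
                   col, student[[col]][[1]], researcher[[col]][[1]]),
           call. = FALSE)
    }
  }
  assert_that(identical(student$role[[1]], "student") &&
                identical(researcher$role[[1]], "researcher"),
              "records must have roles student and researcher")
  ks <- kb_key_elements(kb, student$dx_code[[1]])
  s_valid <- intersect(unique(student$identified_elements[[1]]), ks)
  r_valid <- intersect(unique(researcher$identified_elements[[1]]), ks)
  ns <- length(s_valid)
  nr <- length(r_valid)
  outcome <- if (mode == "set" && !setequal(s_valid, r_valid)) {
    if (ns >= nr) "FP" else "FN"
  } else if (ns == nr) "TP" else if (ns > nr) "FP" else "FN"
  data.frame(participant_id = student$participant_id[[1]],
             group = student$group[[1]],
             phase = student$phase[[1]],
             outcome = outcome,
             compliant = ns >= 3L,
             n_student_valid = ns,
             n_researcher_valid = nr,
             stringsAsFactors = FALSE)
}

#' Classify every student/researcher pair in a cohort
#'
#' Pairs care-plan records by (participant, patient, phase, diagnosis) and
#' applies [classify_participant()] to each pair. Every student record must
#' have exactly one researcher counterpart.
#'
#' @param plans care-plan data frame containing both roles.
#' @param kb a `knowledge_base`.
#' @param mode passed to [classify_participant()].
#' @return data frame of classifications, one row per (participant, phase).
#' @export
classify_cohort <- function(plans, kb, mode = c("count", "set")) {
  mode <- match.arg(mode)
  stopifnot(inherits(kb, "knowledge_base"))
  key <- paste(plans$participant_id, plans$patient_id, plans$phase,
               plans$dx_code, sep = "\r")
  stu <- plans[plans$role == "student", , drop = FALSE]
  res <- plans[plans$role == "researcher", , drop = FALSE]
  skey <- key[plans$role == "student"]
  rkey <- key[plans$role == "researcher"]
  idx <- match(skey, rkey)
  if (anyNA(idx)) {
    stop(sprintf("no researcher record paired with student key (%s)",
                 gsub("\r", ", ", skey[is.na(idx)][1L])), call. = FALSE)
  }
  # vectorized version of classify_participant over all pairs
  key_sets <- new.env(parent = emptyenv())
  n_valid <- function(elements, dx) {
    mapply(function(el, d) {
      ks <- key_sets[[d]] %||% (key_sets[[d]] <- kb_key_elements(kb, d))
      length(intersect(unique(el), ks))
    }, elements, dx)
  }
  ns <- n_valid(stu$identified_elements, stu$dx_code)
  nr <- n_valid(res$identified_elements[idx], res$dx_code[idx])
  outcome <- ifelse(ns == nr, "TP", ifelse(ns > nr, "FP", "FN"))
  if (mode == "set") {
    same_set <- mapply(function(s, r, d) {
      ks <- key_sets[[d]]
      setequal(intersect(unique(s), ks), intersect(unique(r), ks))
    }, stu$identified_elements, res$identified_elements[idx], stu$dx_code)
    outcome <- ifelse(same_set, "TP", ifelse(ns >= nr, "FP", "FN"))
  }
  out <- data.frame(participant_id = stu$participant_id,
                    group = stu$group,
                    phase = stu$phase,
                    outcome = outcome,
                    compliant = ns >= 3L,
                    n_student_valid = as.integer(ns),
                    n_researcher_valid = as.integer(nr),
                    stringsAsFactors = FALSE)
  pkey <- paste(out$participant_id, out$phase)
  if (anyDuplicated(pkey)) {
    stop(sprintf("participant '%s' classified more than once in phase '%s'",
                 out$participant_id[duplicated(pkey)][1L],
                 out$phase[duplicated(pkey)][1L]), call. = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Positive predictive value over participant classifications
#'
#' `PPV = TP / (TP + FP)`: among plans that matched or exceeded the
#' reference, the proportion that matched it exactly.
#'
#' @param tp true-positive count.
#' @param fp false-positive count.
#' @return proportion in \[0, 1\].
#' @export
#' @examples
#' ppv(126, 17)  # 0.88 at 2 decimals
ppv <- function(tp, fp) {
  assert_that(all(tp >= 0) && all(fp >= 0), "counts must be non-negative")
  assert_that(all(tp + fp >= 1), "PPV undefined: TP + FP = 0")
  tp / (tp + fp)
}

#' Sensitivity over participant classifications
#'
#' `sensitivity = TP / (TP + FN)`.
#'
#' @param tp true-positive count.
#' @param fn false-negative count.
#' @return proportion in \[0, 1\].
#' @export
#' @examples
#' sensitivity(174, 305)  # 0.36 at 2 decimals
sensitivity <- function(tp, fn) {
  assert_that(all(tp >= 0) && all(fn >= 0), "counts must be non-negative")
  assert_that(all(tp + fn >= 1), "sensitivity undefined: TP + FN = 0")
  tp / (tp + fn)
}

#' Aggregate classifications into a competency table
#'
#' Per (group, phase): TP/FP/FN counts (which partition the group),
#' compliance count, PPV and sensitivity.
#'
#' @param classifications data frame from [classify_cohort()].
#' @return an object of class `competency_table`: a data frame with columns
#'   `group`, `phase`, `n`, `tp`, `fp`, `fn`, `compliant`, `ppv`,
#'   `sensitivity`.
#' @export
aggregate_competency <- function(classifications) {
  cl <- as.data.frame(classifications)
  pkey <- paste(cl$participant_id, cl$phase)
  if (anyDuplicated(pkey)) {
    stop(sprintf("participant '%s' appears twice in phase '%s'",
                 cl$participant_id[duplicated(pkey)][1L],
                 cl$phase[duplicated(pkey)][1L]), call. = FALSE)
  }
  assert_that(all(cl$outcome %in% c("TP", "FP", "FN")),
              "outcome must be TP, FP or FN")
  g <- interaction(cl$group, cl$phase, drop = TRUE, sep = "\r")
  agg <- function(f) as.vector(tapply(f, g, sum))
  parts <- do.call(rbind, strsplit(levels(g), "\r", fixed = TRUE))
  out <- data.frame(group = parts[, 1], phase = parts[, 2],
                    n = as.vector(table(g)),
                    tp = agg(cl$outcome == "TP"),
                    fp = agg(cl$outcome == "FP"),
                    fn = agg(cl$outcome == "FN"),
                    compliant = agg(cl$compliant),
                    stringsAsFactors = FALSE)
  competency_table(out)
}

#' Build a competency table directly from counts
#'
#' Used to evaluate published or fixture count tables where the
#' per-participant classifications themselves are not available.
#'
#' @param group,phase character vectors (one entry per row).
#' @param tp,fp,fn outcome counts per row; they must sum to the group size.
#' @param compliant optional compliance counts.
#' @param n optional group sizes (default `tp + fp + fn`).
#' @return a `competency_table`.
#' @export
competency_from_counts <- function(group, phase, tp, fp, fn,
                                   compliant = NA_integer_, n = tp + fp + fn) {
  competency_table(data.frame(group = group, phase = phase, n = n,
                              tp = tp, fp = fp, fn = fn,
                              compliant = compliant,
                              stringsAsFactors = FALSE))
}

competency_table <- function(df) {
  assert_that(all(df$tp + df$fp + df$fn == df$n),
              "TP + FP + FN must equal n for every (group, phase)")
  df$ppv <- ppv(df$tp, df$fp)
  df$sensitivity <- sensitivity(df$tp, df$fn)
  df <- df[order(df$phase, match(df$group, GROUPS)), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("competency_table", "data.frame")
  df
}

#' @export
print.competency_table <- function(x, ...) {
  cat("Decision-making competency\n")
  df <- as.data.frame(x)
  df$`tp(%)` <- sprintf("%d (%.2f)", df$tp, round_half_up(100 * df$tp / df$n, 2))
  df$`fp(%)` <- sprintf("%d (%.2f)", df$fp, round_half_up(100 * df$fp / df$n, 2))
  df$`fn(%)` <- sprintf("%d (%.2f)", df$fn, round_half_up(100 * df$fn / df$n, 2))
  df$compliant <- ifelse(is.na(df$compliant), "-",
                         sprintf("%d (%.2f)", df$compliant,
                                 round_half_up(100 * df$compliant / df$n, 2)))
  df$ppv <- sprintf("%.2f", round_half_up(df$ppv, 2))
  df$sensitivity <- sprintf("%.2f", round_half_up(df$sensitivity, 2))
  print(df[c("group", "phase", "n", "tp(%)", "fp(%)", "fn(%)", "compliant",
             "ppv", "sensitivity")], row.names = FALSE)
  invisible(x)
}

#' @export
summary.competency_table <- function(object, ...) {
  df <- as.data.frame(object)
  pooled <- data.frame(group = "pooled", phase = "all",
                       n = sum(df$n), tp = sum(df$tp), fp = sum(df$fp),
                       fn = sum(df$fn),
                       compliant = if (anyNA(df$compliant)) NA_integer_
                                   else sum(df$compliant))
  pooled$ppv <- ppv(pooled$tp, pooled$fp)
  pooled$sensitivity <- sensitivity(pooled$tp, pooled$fn)
  structure(list(table = df, pooled = pooled),
            class = "summary.competency_table")
}

#' @export
print.summary.competency_table <- function(x, ...) {
  print(competency_table(x$table))
  cat(sprintf("\nPooled: n %d, PPV %.2f, sensitivity %.2f\n",
              x$pooled$n, round_half_up(x$pooled$ppv, 2),
              round_half_up(x$pooled$sensitivity, 2)))
  invisible(x)
}
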