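# Clinical Diagnostic Validity (CDV) inference engine: weighted interrater
# reliability ratios from paired junior/senior nurse observations.

#' Tally paired-rater agreement per association
#'
#' For each (assessment item, diagnosis, element) association, counts over
#' the patients observed for it: `F1` patients the junior nurse marked
#' positive, `F2` patients the senior nurse marked positive, `N` patients
#' observed, `A` agreements and `D = N - A` disagreements.
#'
#' Two readings of "agreement" are supported: `both_states` (default; the
#' raters agree when their presence/absence judgments coincide, the usual
#' interrater-reliability convention) and `presence_only` (only joint
#' presence counts as agreement).
#'
#' @param observations data frame with columns `patient_id`, `item_id`,
#'   `dx_code`, `element_id`, `junior_present`, `senior_present` (logical or
#'   0/1). Each (patient, association) pair may appear at most once.
#' @param agreement_mode `"both_states"` or `"presence_only"`.
#' @return data frame with one row per association and columns `item_id`,
#'   `dx_code`, `element_id`, `F1`, `F2`, `N`, `A`, `D`.
#' @export
#' @examples
#' obs <- data.frame(patient_id = paste0("P", 1:10),
#'                   item_id = "I-001", dx_code = "DX-001",
#'                   element_id = "DX-001-E1",
#'                   junior_present = c(rep(1, 8), 0, 0),
#'                   senior_present = c(rep(1, 8), 1, 0))
#' tally_rater_agreement(obs)  # F1 8, F2 9, N 10, A 9, D 1
tally_rater_agreement <- function(observations,
                                  agreement_mode = c("both_states",
                                                     "presence_only")) {
  agreement_mode <- match.arg(agreement_mode)
  obs <- as.data.frame(observations)
  need <- c("patient_id", "item_id", "dx_code", "element_id",
            "junior_present", "senior_present")
  assert_that(all(need %in% names(obs)),
              sprintf("observations missing column(s): %s",
                      paste(setdiff(need, names(obs)), collapse = ", ")))
  if (nrow(obs) == 0L) {
    return(data.frame(item_id = character(), dx_code = character(),
                      element_id = character(), F1 = integer(),
                      N = integer(), A = integer(), D = integer(),
                      F2 = integer())[, c("item_id", "dx_code", "element_id",
                                          "F1", "F2", "N", "A", "D")])
  }
  jr <- as.logical(as.integer(obs$junior_present))
  sr <- as.logical(as.integer(obs$senior_present))
  assert_that(!anyNA(jr) && !anyNA(sr),
              "junior_present/senior_present must be 0/1 or logical")
  assoc <- paste(obs$item_id, obs$dx_code, obs$element_id, sep = "\r")
  pkey <- paste(obs$patient_id, assoc, sep = "\r")
  if (anyDuplicated(pkey)) {
    dup <- obs[duplicated(pkey), , drop = FALSE][1L, ]
    stop(sprintf("duplicate observation for patient '%s', association (%s, %s, %s)",
                 dup$patient_id, dup$item_id, dup$dx_code, dup$element_id),
         call. = FALSE)
  }
  agree <- if (agreement_mode == "both_states") jr == sr else jr & sr
  f <- factor(assoc, levels = unique(assoc))
  out <- data.frame(
    do.call(rbind, strsplit(levels(f), "\r", fixed = TRUE)),
    F1 = as.integer(tapply(jr, f, sum)),
    F2 = as.integer(tapply(sr, f, sum)),
    N = as.integer(tabulate(f)),
    A = as.integer(tapply(agree, f, sum)),
    stringsAsFactors = FALSE)
  names(out)[1:3] <- c("item_id", "dx_code", "element_id")
  out$D <- out$N - out$A
  rownames(out) <- NULL
  out
}

#' CDV weighted interrater reliability ratio
#'
#' The weighted ratio combines how often each of the two raters saw the
#' association with how often they agreed:
#' `R = ((F1/N + F2/N)/2) * (A/(A + D))`.
#'
#' @param F1 junior-rater positive count(s).
#' @param F2 senior-rater positive count(s).
#' @param N number of patients observed; must be >= 1.
#' @param A agreement count(s).
#' @param D disagreement count(s); `A + D` must equal `N`.
#' @return numeric vector of ratios in \[0, 1\].
#' @export
#' @examples
#' cdv_weighted_ratio(8, 9, 10, 8, 2)  # 0.68
cdv_weighted_ratio <- function(F1, F2, N, A, D) {
  n <- max(length(F1), length(F2), length(N), length(A), length(D))
  F1 <- rep_len(F1, n); F2 <- rep_len(F2, n); N <- rep_len(N, n)
  A <- rep_len(A, n); D <- rep_len(D, n)
  assert_that(all(N >= 1), "N must be >= 1 (no patients observed)")
  assert_that(all(A + D == N), "A + D must equal N")
  assert_that(all(c(F1, F2, A, D) >= 0), "counts must be non-negative")
  assert_that(all(F1 <= N) && all(F2 <= N), "F1 and F2 cannot exceed N")
  ((F1 / N + F2 / N) / 2) * (A / (A + D))
}

#' Classify a weighted ratio into major/minor/excluded
#'
#' Ratios of at least 0.80 are major indicators; ratios in \[0.50, 0.80) are
#' minor; anything below 0.50 is excluded from display.
#'
#' @param R numeric vector of ratios in \[0, 1\].
#' @param major major threshold (default 0.80, inclusive).
#' @param minor minor threshold (default 0.50, inclusive).
#' @return character vector: `"major"`, `"minor"` or `"excluded"`.
#' @export
classify_ratio <- function(R, major = 0.80, minor = 0.50) {
  classify_level(R, major = major, minor = minor)
}

#' Build a CDV indicator table from paired-rater observations
#'
#' Tallies agreement per association, computes the weighted interrater
#' reliability ratio and classifies each association. Excluded entries are
#' retained in the table (marked non-displayable) so knowledge-base builds
#' are reproducible.
#'
#' @inheritParams tally_rater_agreement
#' @param kb a `knowledge_base`; observations must resolve against it.
#' @param major,minor classification thresholds.
#' @return an [indicator_table] with `engine = "cdv"`.
#' @export
build_cdv_indicators <- function(observations, kb,
                                 agreement_mode = c("both_states",
                                                    "presence_only"),
                                 major = 0.80, minor = 0.50) {
  agreement_mode <- match.arg(agreement_mode)
  stopifnot(inherits(kb, "knowledge_base"))
  tallies <- tally_rater_agreement(observations, agreement_mode)
  if (nrow(tallies)) {
    check_resolves(tallies, kb, "observation")
    tallies$score <- cdv_weighted_ratio(tallies$F1, tallies$F2, tallies$N,
                                        tallies$A, tallies$D)
    tallies$level <- classify_ratio(tallies$score, major, minor)
  } else {
    tallies$score <- numeric(0)
    tallies$level <- character(0)
  }
  entries <- tallies[c("item_id", "dx_code", "element_id", "score", "level")]
  indicator_table(entries, engine = "cdv",
                  params = list(agreement_mode = agreement_mode,
                                major = major, minor = minor))
}

# associations in a data frame must exist in the kb
check_resolves <- function(df, kb, what) {
  bad <- !(df$item_id %in% kb$assessment_items$item_id)
  if (any(bad)) {
    stop(sprintf("%s references unknown item_id '%s'",
                 what, df$item_id[bad][1L]), call. = FALSE)
  }
  key <- paste(df$dx_code, df$element_id)
  bad <- !(key %in% kb_element_index(kb))
  if (any(bad)) {
    stop(sprintf("%s references element '%s' not in diagnosis '%s'",
                 what, df$element_id[bad][1L], df$dx_code[bad][1L]),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Read paired-rater observations from CSV
#'
#' Columns `patient_id,item_id,dx_code,element_id,junior_present,senior_present`
#' with 0/1 presence tokens.
#'
#' @param path CSV file path.
#' @return data frame of observations.
#' @export
read_rater_observations <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("observation file not found: '%s'", path), call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "item_id", "dx_code", "element_id",
            "junior_present", "senior_present")
  assert_that(all(need %in% names(df)),
              sprintf("observation CSV missing column(s): %s",
                      paste(setdiff(need, names(df)), collapse = ", ")))
  df
}
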