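# Guidance generation: turn a patient's positive assessment findings plus a
# scored indicator table into ranked per-diagnosis element lists, and the
# >= 3-element compliance rule.

#' Generate per-diagnosis guidance for one patient
#'
#' For every positive assessment finding, collects the displayable (major or
#' minor) indicator entries whose assessment item matches, groups them by
#' diagnosis, deduplicates elements keeping the maximum score, and ranks
#' diagnoses by (number of distinct major elements, then sum of scores, then
#' diagnosis code). The result is a deterministic function of its inputs.
#'
#' @param findings data frame with columns `patient_id`, `item_id`,
#'   `present` (logical or 0/1) for a single patient.
#' @param table an [indicator_table] built against `kb`.
#' @param kb a `knowledge_base`.
#' @return an object of class `guidance_list`: a list with `patient_id`,
#'   `entries` (data frame `dx_code`, `element_id`, `score`, `level`,
#'   ordered within diagnosis by level then score) and `ranking` (data frame
#'   `dx_code`, `n_major`, `n_minor`, `score_sum` in rank order).
#' @export
generate_guidance <- function(findings, table, kb) {
  stopifnot(inherits(table, "indicator_table"), inherits(kb, "knowledge_base"))
  findings <- as.data.frame(findings)
  need <- c("patient_id", "item_id", "present")
  assert_that(all(need %in% names(findings)),
              sprintf("findings missing column(s): %s",
                      paste(setdiff(need, names(findings)), collapse = ", ")))
  pid <- unique(findings$patient_id)
  assert_that(length(pid) <= 1L,
              "generate_guidance expects findings for a single patient; split by patient_id")
  bad <- !(findings$item_id %in% kb$assessment_items$item_id)
  if (any(bad)) {
    stop(sprintf("finding references unknown item_id '%s'",
                 findings$item_id[bad][1L]), call. = FALSE)
  }
  pos_items <- unique(findings$item_id[as.logical(as.integer(findings$present))])
  disp <- displayable_entries(table)
  hits <- disp[disp$item_id %in% pos_items, , drop = FALSE]

  if (nrow(hits)) {
    # deduplicate (dx, element) keeping the strongest evidence
    key <- paste(hits$dx_code, hits$element_id, sep = "\r")
    ord <- order(key, -hits$score)
    hits <- hits[ord, , drop = FALSE]
    hits <- hits[!duplicated(key[ord]), , drop = FALSE]
    # within-diagnosis ordering: majors first, then score desc, then id
    hits <- hits[order(hits$dx_code, hits$level != "major", -hits$score,
                       hits$element_id), , drop = FALSE]
    n_major <- tapply(hits$level == "major", hits$dx_code, sum)
    n_minor <- tapply(hits$level == "minor", hits$dx_code, sum)
    score_sum <- tapply(hits$score, hits$dx_code, sum)
    ranking <- data.frame(dx_code = names(n_major),
                          n_major = as.integer(n_major),
                          n_minor = as.integer(n_minor),
                          score_sum = as.numeric(score_sum),
                          stringsAsFactors = FALSE)
    ranking <- ranking[order(-ranking$n_major, -ranking$score_sum,
                             ranking$dx_code), , drop = FALSE]
    # present entries in diagnosis rank order
    hits <- hits[order(match(hits$dx_code, ranking$dx_code)), , drop = FALSE]
    rownames(ranking) <- rownames(hits) <- NULL
  } else {
    hits <- data.frame(item_id = character(), dx_code = character(),
                       element_id = character(), score = numeric(),
                       level = character(), stringsAsFactors = FALSE)
    ranking <- data.frame(dx_code = character(), n_major = integer(),
                          n_minor = integer(), score_sum = numeric(),
                          stringsAsFactors = FALSE)
  }
  structure(list(patient_id = if (length(pid)) pid else NA_character_,
                 entries = hits[c("dx_code", "element_id", "score", "level")],
                 ranking = ranking,
                 engine = attr(table, "engine")),
            class = "guidance_list")
}

#' Unranked control-arm element lists
#'
#' Emulates the care planning system used without guidance indicators: for
#' each diagnosis touched by a positive finding (via the knowledge base's
#' candidate associations), the full taxonomy element list is returned in
#' taxonomy order, unscored and unranked (diagnoses in code order).
#'
#' @inheritParams generate_guidance
#' @return a `guidance_list` with `NA` scores and levels and `engine "none"`.
#' @export
null_guidance <- function(findings, kb) {
  stopifnot(inherits(kb, "knowledge_base"))
  assert_that(!is.null(kb$associations),
              "null_guidance requires candidate associations in the knowledge base")
  findings <- as.data.frame(findings)
  pid <- unique(findings$patient_id)
  assert_that(length(pid) <= 1L,
              "null_guidance expects findings for a single patient")
  pos_items <- unique(findings$item_id[as.logical(as.integer(findings$present))])
  dx <- sort(unique(kb$associations$dx_code[kb$associations$item_id %in% pos_items]))
  entries <- do.call(rbind, lapply(dx, function(code) {
    el <- kb_diagnosis(kb, code)$elements
    data.frame(dx_code = code, element_id = el$element_id,
               score = NA_real_, level = NA_character_,
               stringsAsFactors = FALSE)
  }))
  if (is.null(entries)) {
    entries <- data.frame(dx_code = character(), element_id = character(),
                          score = numeric(), level = character(),
                          stringsAsFactors = FALSE)
  }
  structure(list(patient_id = if (length(pid)) pid else NA_character_,
                 entries = entries,
                 ranking = data.frame(dx_code = dx, n_major = NA_integer_,
                                      n_minor = NA_integer_,
                                      score_sum = NA_real_,
                                      stringsAsFactors = FALSE),
                 engine = "none"),
            class = "guidance_list")
}

#' @export
print.guidance_list <- function(x, max_rows = 10L, ...) {
  cat(sprintf("Guidance for patient '%s' (engine: %s)\n",
              x$patient_id, x$engine))
  if (!nrow(x$ranking)) {
    cat("  no positive findings; no guidance\n")
    return(invisible(x))
  }
  for (i in seq_len(nrow(x$ranking))) {
    r <- x$ranking[i, ]
    if (is.na(r$n_major)) {
      cat(sprintf("  %d. %s (unranked)\n", i, r$dx_code))
    } else {
      cat(sprintf("  %d. %s  (major: %d, minor: %d, score sum: %.2f)\n",
                  i, r$dx_code, r$n_major, r$n_minor, r$score_sum))
    }
    e <- x$entries[x$entries$dx_code == r$dx_code, , drop = FALSE]
    shown <- utils::head(e, max_rows)
    for (j in seq_len(nrow(shown))) {
      if (is.na(shown$score[j])) {
        cat(sprintf("       - %s\n", shown$element_id[j]))
      } else {
        cat(sprintf("       - %s  %.2f (%s)\n", shown$element_id[j],
                    round_half_up(shown$score[j], 2), shown$level[j]))
      }
    }
    if (nrow(e) > max_rows) cat(sprintf("       ... %d more\n",
                                        nrow(e) - max_rows))
  }
  invisible(x)
}

#' Write a guidance list to JSON or TSV
#'
#' @param guidance a `guidance_list`.
#' @param path output path.
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_guidance <- function(guidance, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(guidance, "guidance_list"))
  if (format == "json") {
    out <- list(patient_id = guidance$patient_id, engine = guidance$engine,
                ranking = guidance$ranking, entries = guidance$entries)
    writeLines(jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE, null = "null"), path)
  } else {
    utils::write.table(guidance$entries, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read assessment findings from CSV
#'
#' Columns `patient_id,item_id,present` with 0/1 tokens.
#'
#' @param path CSV file path.
#' @return data frame of findings.
#' @export
read_findings <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("findings file not found: '%s'", path), call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "item_id", "present")
  assert_that(all(need %in% names(df)),
              sprintf("findings CSV missing column(s): %s",
                      paste(setdiff(need, names(df)), collapse = ", ")))
  df
}

#' Is a care plan adequately supported?
#'
#' A plan is adequately supported (an "accurate" diagnosis) when it cites at
#' least `min_elements` distinct elements that belong to the diagnosis's
#' taxonomy list: defining characteristics for actual diagnoses, risk
#' factors for risk diagnoses. Out-of-taxonomy (flagged invalid) elements
#' never count.
#'
#' @param plans care-plan data frame as returned by [read_care_plans()] (or
#'   any data frame with `dx_code` and list-column `identified_elements`).
#' @param kb a `knowledge_base`.
#' @param min_elements minimum distinct supporting elements (default 3).
#' @return logical vector, one value per plan row.
#' @export
adequately_supported <- function(plans, kb, min_elements = 3L) {
  stopifnot(inherits(kb, "knowledge_base"))
  count_valid_elements(plans, kb) >= min_elements
}

# distinct identified elements on the diagnosis's compliance-relevant
# taxonomy list (DCs for actual, risk factors for risk diagnoses)
count_valid_elements <- function(plans, kb) {
  key_sets <- new.env(parent = emptyenv())
  vapply(seq_len(nrow(plans)), function(i) {
    dx <- plans$dx_code[[i]]
    ks <- key_sets[[dx]] %||% (key_sets[[dx]] <- kb_key_elements(kb, dx))
    length(intersect(unique(plans$identified_elements[[i]]), ks))
  }, integer(1))
}
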