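# Knowledge-base data model: construction, validation, JSON (de)serialization,
# and care-plan CSV reading.

#' The five aspects of the psychiatric nursing assessment framework
#'
#' Every assessment item belongs to exactly one of these five aspects of a
#' holistic psychiatric nursing assessment.
#'
#' @export
KB_ASPECTS <- c("physical", "psychological", "social", "developmental",
                "spiritual")

KB_SCHEMA_VERSION <- "1.0"

ELEMENT_TYPES <- c("defining_characteristic", "related_factor", "risk_factor")
DX_TYPES <- c("actual", "risk")
GROUPS <- c("control", "cdv", "bade")
PHASES <- c("pretest", "posttest")
ROLES <- c("student", "researcher")

#' Construct a knowledge base
#'
#' A knowledge base holds a diagnosis taxonomy (each diagnosis with its
#' defining characteristics and, depending on type, related or risk factors),
#' the assessment items of the five-aspect framework, the candidate
#' associations between assessment items and diagnosis elements that an
#' inference engine scores, and optionally a scored indicator table.
#'
#' @param diagnoses list of diagnoses; each a list with fields `dx_code`,
#'   `label`, `dx_type` (`"actual"` or `"risk"`), and `elements`, a data frame
#'   with columns `element_id`, `element_type`, `label`.
#' @param assessment_items data frame with columns `item_id`, `aspect`,
#'   `label`; `aspect` must be one of [KB_ASPECTS].
#' @param associations optional data frame with columns `item_id`, `dx_code`,
#'   `element_id`: the candidate links an engine scores.
#' @param indicators optional [indicator_table] built against this base.
#' @param meta optional list of provenance fields (engine name, build
#'   parameters, seed); `schema_version` is filled in automatically.
#' @return an object of class `knowledge_base`.
#' @seealso [validate_knowledge_base()], [load_knowledge_base()],
#'   [generate_mock_kb()]
#' @export
knowledge_base <- function(diagnoses, assessment_items, associations = NULL,
                           indicators = NULL, meta = list()) {
  meta$schema_version <- meta$schema_version %||% KB_SCHEMA_VERSION
  kb <- structure(
    list(meta = meta,
         assessment_items = as.data.frame(assessment_items),
         diagnoses = diagnoses,
         associations = if (!is.null(associations)) as.data.frame(associations),
         indicators = indicators),
    class = "knowledge_base")
  violations <- validate_knowledge_base(kb)
  if (length(violations)) {
    stop("invalid knowledge base:\n  ", paste(violations, collapse = "\n  "),
         call. = FALSE)
  }
  kb
}

#' Validate a knowledge base
#'
#' Checks every structural invariant and returns violations as data rather
#' than raising: unique item and diagnosis identifiers, aspects drawn from
#' the five-aspect framework, element types consistent with the diagnosis
#' type, at least three defining characteristics (or risk factors) per
#' diagnosis so the compliance rule is satisfiable, and no dangling
#' association or indicator references.
#'
#' @param kb a `knowledge_base` (possibly not yet validated).
#' @return character vector of violation descriptions; empty iff the base is
#'   valid. Each violation names the offending entity and the rule broken.
#' @export
validate_knowledge_base <- function(kb) {
  v <- character()
  items <- kb$assessment_items
  if (!all(c("item_id", "aspect", "label") %in% names(items))) {
    return("assessment_items: missing required columns item_id/aspect/label")
  }
  if (anyDuplicated(items$item_id)) {
    v <- c(v, sprintf("assessment item '%s': duplicated item_id",
                      items$item_id[duplicated(items$item_id)][1L]))
  }
  bad_aspect <- setdiff(unique(items$aspect), KB_ASPECTS)
  if (length(bad_aspect)) {
    v <- c(v, sprintf("assessment items: unknown aspect '%s' (must be one of the 5 framework aspects)",
                      bad_aspect[1L]))
  }

  codes <- vapply(kb$diagnoses, function(d) d$dx_code %||% NA_character_,
                  character(1))
  if (anyDuplicated(codes)) {
    v <- c(v, sprintf("diagnosis '%s': duplicated dx_code",
                      codes[duplicated(codes)][1L]))
  }
  for (d in kb$diagnoses) {
    el <- d$elements
    if (is.null(el) || nrow(el) == 0L) {
      v <- c(v, sprintf("diagnosis '%s': has no elements", d$dx_code))
      next
    }
    if (anyDuplicated(el$element_id)) {
      v <- c(v, sprintf("diagnosis '%s': duplicated element_id '%s'",
                        d$dx_code, el$element_id[duplicated(el$element_id)][1L]))
    }
    bad_type <- setdiff(unique(el$element_type), ELEMENT_TYPES)
    if (length(bad_type)) {
      v <- c(v, sprintf("diagnosis '%s': unknown element_type '%s'",
                        d$dx_code, bad_type[1L]))
    }
    if (!(d$dx_type %in% DX_TYPES)) {
      v <- c(v, sprintf("diagnosis '%s': unknown dx_type '%s'",
                        d$dx_code, d$dx_type))
      next
    }
    # the >= 3 supporting-element rule must be satisfiable
    key_type <- if (d$dx_type == "risk") "risk_factor" else "defining_characteristic"
    n_key <- sum(el$element_type == key_type)
    if (n_key < 3L) {
      v <- c(v, sprintf(
        "diagnosis '%s': compliance rule unsatisfiable (%d %s(s), need >= 3)",
        d$dx_code, n_key, key_type))
    }
    if (d$dx_type == "risk" && any(el$element_type == "defining_characteristic")) {
      v <- c(v, sprintf("diagnosis '%s': risk-type diagnosis carries defining characteristics",
                        d$dx_code))
    }
  }

  el_index <- kb_element_index(kb)
  check_assoc <- function(df, what) {
    out <- character()
    bad_item <- !(df$item_id %in% items$item_id)
    if (any(bad_item)) {
      out <- c(out, sprintf("%s: item_id '%s' not in assessment items",
                            what, df$item_id[bad_item][1L]))
    }
    key <- paste(df$dx_code, df$element_id)
    bad_el <- !(key %in% el_index)
    if (any(bad_el)) {
      out <- c(out, sprintf("%s: element '%s' not in diagnosis '%s'",
                            what, df$element_id[bad_el][1L],
                            df$dx_code[bad_el][1L]))
    }
    out
  }
  if (!is.null(kb$associations) && nrow(kb$associations)) {
    v <- c(v, check_assoc(kb$associations, "association"))
  }
  if (!is.null(kb$indicators) && nrow(kb$indicators$entries)) {
    v <- c(v, check_assoc(kb$indicators$entries, "indicator"))
  }
  v
}

# "dx_code element_id" keys of all elements in the base
kb_element_index <- function(kb) {
  unlist(lapply(kb$diagnoses, function(d) {
    paste(d$dx_code, d$elements$element_id)
  }), use.names = FALSE)
}

#' Look up one diagnosis of a knowledge base
#'
#' @param kb a `knowledge_base`.
#' @param dx_code diagnosis code.
#' @return the diagnosis (list with `dx_code`, `label`, `dx_type`,
#'   `elements`); error if the code is unknown.
#' @export
kb_diagnosis <- function(kb, dx_code) {
  for (d in kb$diagnoses) if (identical(d$dx_code, dx_code)) return(d)
  stop(sprintf("unknown dx_code '%s'", dx_code), call. = FALSE)
}

# element ids that count toward the compliance rule for a diagnosis:
# defining characteristics for actual diagnoses, risk factors for risk ones
kb_key_elements <- function(kb, dx_code) {
  d <- kb_diagnosis(kb, dx_code)
  key_type <- if (d$dx_type == "risk") "risk_factor" else "defining_characteristic"
  d$elements$element_id[d$elements$element_type == key_type]
}

#' @export
print.knowledge_base <- function(x, ...) {
  n_el <- sum(vapply(x$diagnoses, function(d) nrow(d$elements), integer(1)))
  cat(sprintf(
    "Knowledge base (schema %s): %d diagnoses, %d elements, %d assessment items\n",
    x$meta$schema_version, length(x$diagnoses), n_el,
    nrow(x$assessment_items)))
  if (!is.null(x$associations)) {
    cat(sprintf("  %d candidate item-element associations\n",
                nrow(x$associations)))
  }
  if (!is.null(x$indicators)) {
    cat(sprintf("  indicator table present (engine: %s)\n",
                attr(x$indicators, "engine")))
  }
  if (!is.null(x$meta$engine)) cat(sprintf("  engine: %s\n", x$meta$engine))
  if (!is.null(x$meta$seed)) cat(sprintf("  seed: %s\n", x$meta$seed))
  invisible(x)
}

# ---- JSON serialization ----------------------------------------------------

kb_to_list <- function(kb) {
  list(
    meta = kb$meta,
    assessment_items = kb$assessment_items,
    diagnoses = lapply(kb$diagnoses, function(d) {
      list(dx_code = d$dx_code, label = d$label, dx_type = d$dx_type,
           elements = d$elements)
    }),
    associations = kb$associations,
    indicators = if (!is.null(kb$indicators)) {
      list(engine = attr(kb$indicators, "engine"),
           params = attr(kb$indicators, "params"),
           entries = kb$indicators$entries)
    }
  )
}

#' Write a knowledge base to JSON
#'
#' The on-disk format has top-level keys `meta`, `assessment_items`,
#' `diagnoses`, `associations` and `indicators`, with `schema_version` under
#' `meta`. Writing then reloading yields a content-identical file.
#'
#' @param kb a `knowledge_base`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_knowledge_base <- function(kb, path) {
  json <- jsonlite::toJSON(kb_to_list(kb), auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null")
  writeLines(json, path)
  invisible(path)
}

#' Load a knowledge base from JSON
#'
#' Reads and validates a knowledge base written by [write_knowledge_base()]
#' (or any file following the same schema). Schema violations are reported
#' with a JSON-pointer-style path to the first offending node; dangling
#' association or indicator references are rejected.
#'
#' @param path path to a knowledge-base JSON file.
#' @return a validated `knowledge_base`.
#' @export
load_knowledge_base <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("knowledge base file not found: '%s'", path), call. = FALSE)
  }
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE,
                            simplifyVector = TRUE)
  for (key in c("meta", "assessment_items", "diagnoses")) {
    if (is.null(raw[[key]])) {
      stop(sprintf("schema violation at /%s: required key missing", key),
           call. = FALSE)
    }
  }
  items <- as.data.frame(raw$assessment_items)
  need <- c("item_id", "aspect", "label")
  if (!all(need %in% names(items))) {
    stop(sprintf("schema violation at /assessment_items: missing column '%s'",
                 setdiff(need, names(items))[1L]), call. = FALSE)
  }
  dx_raw <- raw$diagnoses
  # jsonlite simplifies an array of objects to a data frame with a
  # list-column of element data frames; normalise back to a list
  if (is.data.frame(dx_raw)) {
    dx_list <- lapply(seq_len(nrow(dx_raw)), function(i) {
      list(dx_code = dx_raw$dx_code[[i]], label = dx_raw$label[[i]],
           dx_type = dx_raw$dx_type[[i]],
           elements = as.data.frame(dx_raw$elements[[i]]))
    })
  } else {
    dx_list <- lapply(dx_raw, function(d) {
      d$elements <- as.data.frame(d$elements)
      d
    })
  }
  for (i in seq_along(dx_list)) {
    d <- dx_list[[i]]
    if (is.null(d$dx_code) || is.null(d$dx_type)) {
      stop(sprintf("schema violation at /diagnoses/%d: missing dx_code or dx_type",
                   i - 1L), call. = FALSE)
    }
    if (!all(c("element_id", "element_type") %in% names(d$elements))) {
      stop(sprintf("schema violation at /diagnoses/%d/elements: missing element_id or element_type",
                   i - 1L), call. = FALSE)
    }
  }
  assoc <- if (!is.null(raw$associations)) as.data.frame(raw$associations)
  ind <- NULL
  if (!is.null(raw$indicators)) {
    ind <- indicator_table(as.data.frame(raw$indicators$entries),
                           engine = raw$indicators$engine,
                           params = raw$indicators$params)
  }
  kb <- structure(
    list(meta = raw$meta, assessment_items = items, diagnoses = dx_list,
         associations = assoc, indicators = ind),
    class = "knowledge_base")
  violations <- validate_knowledge_base(kb)
  if (length(violations)) {
    stop("invalid knowledge base in '", path, "':\n  ",
         paste(violations, collapse = "\n  "), call. = FALSE)
  }
  kb
}

# ---- care plans ------------------------------------------------------------

#' Read care-plan records from CSV
#'
#' One row per (participant, phase, role, diagnosis), with columns
#' `participant_id,patient_id,group,phase,role,dx_code,identified_elements`;
#' `identified_elements` is a `|`-separated list of element ids. Identified
#' elements that do not belong to the stated diagnosis in `kb` are retained
#' but flagged invalid (they count as evidence of over-identification in the
#' competency evaluation, never as taxonomy support).
#'
#' @param path CSV file path.
#' @param kb a `knowledge_base` used to resolve element ids; if `NULL`, no
#'   validity flagging is done and all elements are taken at face value.
#' @return data frame of care-plan records with list-columns
#'   `identified_elements` (all ids, as recorded) and `invalid_elements`
#'   (the subset not found in the diagnosis's taxonomy).
#' @export
read_care_plans <- function(path, kb = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("care-plan file not found: '%s'", path), call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("participant_id", "patient_id", "group", "phase", "role",
            "dx_code", "identified_elements")
  if (!all(need %in% names(df))) {
    stop(sprintf("care-plan CSV missing column(s): %s",
                 paste(setdiff(need, names(df)), collapse = ", ")),
         call. = FALSE)
  }
  check_token <- function(col, allowed) {
    bad <- setdiff(unique(df[[col]]), allowed)
    if (length(bad)) {
      stop(sprintf("care-plan CSV: unknown %s token '%s'", col, bad[1L]),
           call. = FALSE)
    }
  }
  check_token("group", GROUPS)
  check_token("phase", PHASES)
  check_token("role", ROLES)
  key <- paste(df$participant_id, df$phase, df$role, df$dx_code)
  if (anyDuplicated(key)) {
    stop(sprintf("care-plan CSV: duplicate record for key (%s)",
                 key[duplicated(key)][1L]), call. = FALSE)
  }
  plans <- care_plan_frame(df, kb)
  plans
}

# split identified_elements and flag out-of-taxonomy ids against kb
care_plan_frame <- function(df, kb = NULL) {
  ids <- strsplit(df$identified_elements, "|", fixed = TRUE)
  ids <- lapply(ids, function(x) x[nzchar(x)])
  if (!is.null(kb)) {
    valid_sets <- lapply(kb$diagnoses, function(d) d$elements$element_id)
    names(valid_sets) <- vapply(kb$diagnoses, `[[`, character(1), "dx_code")
    invalid <- mapply(function(el, dx) {
      vs <- valid_sets[[dx]]
      if (is.null(vs)) el else setdiff(el, vs)
    }, ids, df$dx_code, SIMPLIFY = FALSE)
  } else {
    invalid <- rep(list(character()), length(ids))
  }
  out <- df[c("participant_id", "patient_id", "group", "phase", "role",
              "dx_code")]
  out$identified_elements <- ids
  out$invalid_elements <- invalid
  class(out) <- c("care_plans", "data.frame")
  out
}

#' Write care-plan records to CSV
#'
#' Inverse of [read_care_plans()]: list-columns are re-joined with `|`.
#'
#' @param plans care-plan data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_care_plans <- function(plans, path) {
  df <- plans[c("participant_id", "patient_id", "group", "phase", "role",
                "dx_code")]
  df$identified_elements <- vapply(plans$identified_elements,
                                   paste, character(1), collapse = "|")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
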