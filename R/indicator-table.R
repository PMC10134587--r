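# Shared indicator-table container used by both inference engines.

#' Construct an indicator table
#'
#' An indicator table is the scored knowledge-base product of an inference
#' engine: one row per (assessment item, diagnosis, element) association
#' with a score in \[0, 1\] and a level (`major`, `minor` or `excluded`).
#' Excluded entries are retained for reproducibility of knowledge-base
#' builds but are never emitted as guidance.
#'
#' @param entries data frame with columns `item_id`, `dx_code`,
#'   `element_id`, `score`, `level`.
#' @param engine `"cdv"`, `"bayes"` or `"none"` (the unscored control-arm
#'   engine).
#' @param params list of build parameters (thresholds, smoothing, ...).
#' @return an object of class `indicator_table` (a list with element
#'   `entries`, attributes `engine` and `params`).
#' @export
indicator_table <- function(entries, engine, params = list()) {
  entries <- as.data.frame(entries)
  need <- c("item_id", "dx_code", "element_id", "score", "level")
  if (nrow(entries) == 0L) {
    entries <- data.frame(item_id = character(), dx_code = character(),
                          element_id = character(), score = numeric(),
                          level = character(), stringsAsFactors = FALSE)
  }
  assert_that(all(need %in% names(entries)),
              sprintf("indicator entries missing column(s): %s",
                      paste(setdiff(need, names(entries)), collapse = ", ")))
  key <- paste(entries$item_id, entries$dx_code, entries$element_id)
  assert_that(!anyDuplicated(key),
              "indicator table: duplicated association entry")
  ok_level <- entries$level %in% c("major", "minor", "excluded")
  assert_that(all(ok_level | is.na(entries$level)),
              "indicator table: level must be major/minor/excluded")
  structure(list(entries = entries),
            engine = engine, params = params, class = "indicator_table")
}

#' @export
print.indicator_table <- function(x, ...) {
  tab <- table(factor(x$entries$level,
                      levels = c("major", "minor", "excluded")))
  cat(sprintf("Indicator table (engine: %s): %d associations\n",
              attr(x, "engine"), nrow(x$entries)))
  cat(sprintf("  major: %d   minor: %d   excluded: %d\n",
              tab[["major"]], tab[["minor"]], tab[["excluded"]]))
  invisible(x)
}

#' @export
summary.indicator_table <- function(object, ...) {
  e <- object$entries
  out <- list(engine = attr(object, "engine"),
              n = nrow(e),
              by_level = table(factor(e$level,
                                      levels = c("major", "minor", "excluded"))),
              score_range = if (nrow(e)) range(e$score) else c(NA, NA))
  class(out) <- "summary.indicator_table"
  out
}

#' @export
print.summary.indicator_table <- function(x, ...) {
  cat(sprintf("Indicator table summary (engine: %s)\n", x$engine))
  cat(sprintf("  associations: %d\n", x$n))
  print(x$by_level)
  if (!is.na(x$score_range[1])) {
    cat(sprintf("  score range: [%.3f, %.3f]\n",
                x$score_range[1], x$score_range[2]))
  }
  invisible(x)
}

#' Displayable entries of an indicator table
#'
#' The guidance screen shows major and minor indicators together; excluded
#' entries (score below the minor threshold) are kept in the table but never
#' displayed.
#'
#' @param table an `indicator_table`.
#' @return data frame of entries with `level` of `major` or `minor`.
#' @export
displayable_entries <- function(table) {
  stopifnot(inherits(table, "indicator_table"))
  table$entries[table$entries$level %in% c("major", "minor"), , drop = FALSE]
}

# shared level classification for a score vector given thresholds
classify_level <- function(score, major = 0.80, minor = 0.50) {
  assert_that(is.numeric(score), "score must be numeric")
  check_prob(score, "score")
  assert_that(minor < major, "minor threshold must be below major threshold")
  ifelse(score >= major, "major", ifelse(score >= minor, "minor", "excluded"))
}
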