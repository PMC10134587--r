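# Study reproduction: recompute every desk-reproducible published quantity
# from the shipped count/summary fixtures and diff against the printed
# values.

#' Path to the shipped fixture tables
#'
#' @return directory containing `table1_counts.json`, `table4_counts.json`
#'   and `table2_summaries.json`.
#' @export
fixture_dir <- function() {
  system.file("extdata", package = "kbcdss")
}

#' Recompute the published competency and statistics tables
#'
#' Loads the shipped (or user-supplied) fixture count tables, recomputes
#' percentages, PPV, sensitivity, the between-group chi-square statistics,
#' the summary-statistic ANOVA F values and the Scheffe orderings with this
#' package's own routines, and diffs each value against the printed one.
#' Proportions and chi-squares are compared exactly at two decimals
#' (half-up rounding). ANOVA F values are recomputed from printed (n, mean,
#' SD) triples, so they inherit the rounding of those summaries: the
#' baseline age F is compared within 0.5 percent and the questionnaire F
#' values within 2 percent (the questionnaire means are printed to two
#' decimals and their between-group differences are small, so two-decimal
#' rounding alone can move the recomputed F by over one percent).
#'
#' @param fixtures path to a directory holding the three fixture files
#'   (default: the copies shipped with the package).
#' @return an object of class `reproduction_report`: a data frame with one
#'   row per recomputed quantity (`quantity`, `computed`, `printed`,
#'   `match`) and attribute `ok` (all rows match).
#' @export
run_study_reproduction <- function(fixtures = fixture_dir()) {
  t1 <- read_fixture(file.path(fixtures, "table1_counts.json"))
  t4 <- read_fixture(file.path(fixtures, "table4_counts.json"))
  t2 <- read_fixture(file.path(fixtures, "table2_summaries.json"))

  rows <- list()
  add <- function(quantity, computed, printed, digits = 2, rel_tol = NULL) {
    match <- if (is.character(computed)) {
      identical(computed, printed)
    } else if (!is.null(rel_tol)) {
      abs(computed - printed) <= rel_tol * abs(printed)
    } else {
      abs(round_half_up(computed, digits) - printed) < 1e-9
    }
    rows[[length(rows) + 1L]] <<- data.frame(
      quantity = quantity,
      computed = if (is.character(computed)) computed
                 else format(computed, digits = 15),
      printed = if (is.character(printed)) printed else format(printed),
      match = match, stringsAsFactors = FALSE)
  }

  for (tab in list(t1, t4)) {
    nm <- tab$table
    n <- tab$n
    for (outcome in names(tab$counts)) {
      x <- tab$counts[[outcome]]
      # group percentages
      for (i in seq_along(tab$groups)) {
        add(sprintf("%s %s %% (%s)", nm, outcome, tab$groups[i]),
            100 * x[i] / n[i], tab$printed$percent[[outcome]][i])
      }
      # between-group chi-square on the 2 x 3 outcome table
      chi <- pearson_chi_square(rbind(x, n - x))
      add(sprintf("%s chi-square (%s)", nm, outcome),
          chi$statistic, tab$printed$chi_square[[outcome]])
    }
    tp <- tab$counts$true_positive
    fp <- tab$counts$false_positive
    fn <- tab$counts$false_negative
    for (i in seq_along(tab$groups)) {
      add(sprintf("%s PPV (%s)", nm, tab$groups[i]),
          ppv(tp[i], fp[i]), tab$printed$ppv[i])
      add(sprintf("%s sensitivity (%s)", nm, tab$groups[i]),
          sensitivity(tp[i], fn[i]), tab$printed$sensitivity[i])
    }
    if (!is.null(tab$printed$ppv_pooled)) {
      add(sprintf("%s PPV (pooled)", nm), ppv(sum(tp), sum(fp)),
          tab$printed$ppv_pooled)
      add(sprintf("%s sensitivity (pooled)", nm),
          sensitivity(sum(tp), sum(fn)), tab$printed$sensitivity_pooled)
    }
  }

  age <- t1$age_summary
  add("pretest age ANOVA F",
      anova_from_summary(age$n, age$mean, age$sd)$statistic,
      age$printed_f, rel_tol = 0.005)

  for (i in seq_len(nrow(t2$rows))) {
    r <- t2$rows[i, ]
    fit <- anova_from_summary(t2$n, r$mean[[1]], r$sd[[1]])
    add(sprintf("posttest %s ANOVA F", r$dimension), fit$statistic,
        r$printed_f, rel_tol = 0.02)
    sch <- scheffe_posthoc(t2$n, r$mean[[1]], r$sd[[1]])
    add(sprintf("posttest %s Scheffe ordering", r$dimension),
        sch$ordering, r$printed_ordering)
  }

  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  structure(report, ok = all(report$match),
            class = c("reproduction_report", "data.frame"))
}

read_fixture <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("fixture not found: '%s'", path), call. = FALSE)
  }
  jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
}

#' @export
print.reproduction_report <- function(x, ...) {
  df <- as.data.frame(x)
  n_bad <- sum(!df$match)
  cat(sprintf("Study reproduction report: %d quantities recomputed, %s\n",
              nrow(df),
              if (n_bad == 0) "all match the printed values"
              else sprintf("%d MISMATCH(ES)", n_bad)))
  if (n_bad > 0) {
    cat("\nMismatching cells:\n")
    print(df[!df$match, ], row.names = FALSE)
  }
  invisible(x)
}
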