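# The study's statistical battery: Pearson chi-square, McNemar-Bowker
# symmetry test, one-way ANOVA from (n, mean, SD) summaries, one-covariate
# ANCOVA, Scheffe post hoc comparisons, and noncentral-F power / sample-size
# calculation. The summary-statistic routines are implemented directly so
# that printed test statistics can be recomputed from printed tables.

kbcdss_test <- function(statistic, df, p.value, method, note = NULL) {
  structure(list(statistic = statistic, df = df, p.value = p.value,
                 method = method, note = note),
            class = "kbcdss_test")
}

#' @export
print.kbcdss_test <- function(x, ...) {
  cat(x$method, "\n")
  if (is.na(x$statistic)) {
    cat("  statistic undefined:", x$note %||% "", "\n")
    return(invisible(x))
  }
  dfs <- paste(x$df, collapse = ", ")
  cat(sprintf("  statistic = %.4f, df = %s, p %s\n", x$statistic, dfs,
              ifelse(substr(format_p(x$p.value), 1, 1) == "<",
                     format_p(x$p.value), paste("=", format_p(x$p.value)))))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Pearson chi-square test of independence
#'
#' `X^2 = sum((O - E)^2 / E)` with expected counts from the row/column
#' margins, `df = (r - 1)(c - 1)`, and no continuity correction (the
#' convention under which the published 2 x 3 statistics reproduce).
#'
#' @param t integer matrix of counts, at least 2 x 2.
#' @return a `kbcdss_test` with the statistic, df and upper-tail p-value.
#' @export
#' @examples
#' n <- c(206, 203, 198); x <- c(155, 191, 172)
#' pearson_chi_square(rbind(x, n - x))  # 29.57
pearson_chi_square <- function(t) {
  t <- as.matrix(t)
  assert_that(nrow(t) >= 2 && ncol(t) >= 2,
              "contingency table must be at least 2 x 2")
  assert_that(all(t >= 0), "cell counts must be non-negative")
  E <- outer(rowSums(t), colSums(t)) / sum(t)
  if (any(E <= 0)) {
    stop("zero expected cell count: chi-square undefined", call. = FALSE)
  }
  stat <- sum((t - E)^2 / E)
  df <- (nrow(t) - 1) * (ncol(t) - 1)
  kbcdss_test(stat, df, stats::pchisq(stat, df, lower.tail = FALSE),
              "Pearson chi-square test (no continuity correction)")
}

#' McNemar-Bowker symmetry test for paired categories
#'
#' For a square k x k table of paired pre/post counts, Bowker's statistic
#' `sum_{i<j} (n_ij - n_ji)^2 / (n_ij + n_ji)` with `df = k(k-1)/2`; pairs
#' with both off-diagonal cells zero contribute nothing and drop one degree
#' of freedom. The 2 x 2 case is McNemar's `(b - c)^2 / (b + c)` without
#' continuity correction. If every discordant pair is zero the test is
#' undefined and reported as such (statistic `NA`).
#'
#' @param t square integer matrix of paired counts.
#' @return a `kbcdss_test`.
#' @export
#' @examples
#' mcnemar_bowker(matrix(c(20, 2, 10, 30), 2))  # (10 - 2)^2 / 12 = 5.33
mcnemar_bowker <- function(t) {
  t <- as.matrix(t)
  assert_that(nrow(t) == ncol(t), "paired-category table must be square")
  assert_that(all(t >= 0), "cell counts must be non-negative")
  k <- nrow(t)
  stat <- 0
  df <- 0L
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      s <- t[i, j] + t[j, i]
      if (s > 0) {
        stat <- stat + (t[i, j] - t[j, i])^2 / s
        df <- df + 1L
      }
    }
  }
  if (df == 0L) {
    return(kbcdss_test(NA_real_, 0L, NA_real_,
                       "McNemar-Bowker symmetry test",
                       note = "all discordant pairs are zero; test undefined"))
  }
  kbcdss_test(stat, df, stats::pchisq(stat, df, lower.tail = FALSE),
              "McNemar-Bowker symmetry test (no continuity correction)")
}

#' One-way ANOVA from group summary statistics
#'
#' Reconstructs the F-test from per-group (n, mean, SD):
#' `SSB = sum n_i (m_i - m)^2` with `m` the n-weighted grand mean,
#' `SSW = sum (n_i - 1) sd_i^2`, `F = (SSB/(k-1)) / (SSW/(N-k))`. Identical
#' to a raw-data one-way ANOVA whenever the summaries are exact.
#'
#' @param n integer vector of group sizes (each >= 2).
#' @param mean numeric vector of group means.
#' @param sd numeric vector of group standard deviations.
#' @return a `kbcdss_test` with `df = c(k - 1, N - k)`; if `SSW = 0` with
#'   `SSB > 0` the statistic is infinite with p-value 0.
#' @export
#' @examples
#' anova_from_summary(c(206, 203, 198), c(21.30, 21.59, 21.53),
#'                    c(1.44, 1.49, 2.00))  # F = 1.74
anova_from_summary <- function(n, mean, sd) {
  assert_that(length(n) >= 2, "need at least 2 groups")
  assert_that(length(mean) == length(n) && length(sd) == length(n),
              "n, mean and sd must have equal length")
  assert_that(all(n >= 2), "each group needs n >= 2")
  assert_that(all(sd >= 0), "standard deviations must be non-negative")
  k <- length(n)
  N <- sum(n)
  gm <- sum(n * mean) / N
  ssb <- sum(n * (mean - gm)^2)
  ssw <- sum((n - 1) * sd^2)
  df <- c(k - 1, N - k)
  if (ssw == 0) {
    if (ssb == 0) {
      return(kbcdss_test(0, df, 1, "One-way ANOVA from summary statistics"))
    }
    return(kbcdss_test(Inf, df, 0, "One-way ANOVA from summary statistics",
                       note = "zero within-group variance"))
  }
  f <- (ssb / df[1]) / (ssw / df[2])
  out <- kbcdss_test(f, df, stats::pf(f, df[1], df[2], lower.tail = FALSE),
                     "One-way ANOVA from summary statistics")
  out$msw <- ssw / df[2]
  out
}

#' One-covariate ANCOVA group test
#'
#' Fits `outcome ~ covariate + group` by least squares and tests the group
#' effect adjusted for the covariate (Type III sum of squares for group,
#' which for a single factor after one covariate is the model-comparison F
#' against `outcome ~ covariate`), with `df = (k - 1, N - k - 1)`.
#'
#' @param records data frame with columns `group` (factor or character),
#'   `covariate` and `outcome` (numeric).
#' @return a `kbcdss_test`.
#' @export
ancova_one_covariate <- function(records) {
  df <- as.data.frame(records)
  need <- c("group", "covariate", "outcome")
  assert_that(all(need %in% names(df)),
              sprintf("records missing column(s): %s",
                      paste(setdiff(need, names(df)), collapse = ", ")))
  df$group <- factor(df$group)
  k <- nlevels(df$group)
  assert_that(k >= 2, "need at least 2 groups")
  assert_that(stats::var(df$covariate) > 0,
              "covariate does not vary; ANCOVA undefined")
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  full <- stats::lm(outcome ~ covariate + group, data = df)
  if (any(is.na(stats::coef(full)))) {
    stop("collinear covariate/group encoding: group effect not estimable",
         call. = FALSE)
  }
  reduced <- stats::lm(outcome ~ covariate, data = df)
  rss_full <- sum(stats::residuals(full)^2)
  rss_red <- sum(stats::residuals(reduced)^2)
  df1 <- k - 1
  df2 <- nrow(df) - k - 1
  f <- ((rss_red - rss_full) / df1) / (rss_full / df2)
  kbcdss_test(f, c(df1, df2),
              stats::pf(f, df1, df2, lower.tail = FALSE),
              "ANCOVA group effect (one covariate, Type III)")
}

#' Scheffe post hoc pairwise comparisons
#'
#' Flags pair (i, j) significant when
#' `(m_i - m_j)^2 / (MSW (1/n_i + 1/n_j)) > (k - 1) F_crit(alpha; k-1, N-k)`
#' and encodes the resulting ordering (e.g. `"a < c < b"` when all pairs
#' separate, or a `;`-joined list of the significant pairs otherwise).
#' Group labels default to letters in input order, matching the convention
#' of labelling the control, first and second intervention arms a, b, c.
#'
#' @param n,mean,sd per-group summaries as in [anova_from_summary()].
#' @param msw mean square within; computed from `sd` when `NULL`.
#' @param alpha family-wise significance level.
#' @param labels group labels (default `letters` in input order).
#' @return an object of class `scheffe_test`: list with `pairs` (data frame
#'   of all pairwise contrasts with test statistics and significance) and
#'   `ordering` (character encoding).
#' @export
scheffe_posthoc <- function(n, mean, sd = NULL, msw = NULL, alpha = 0.05,
                            labels = letters[seq_along(n)]) {
  k <- length(n)
  assert_that(k >= 2, "need at least 2 groups")
  if (is.null(msw)) {
    assert_that(!is.null(sd), "provide either sd or msw")
    msw <- sum((n - 1) * sd^2) / (sum(n) - k)
  }
  assert_that(msw > 0, "mean square within must be positive")
  N <- sum(n)
  fcrit <- stats::qf(1 - alpha, k - 1, N - k)
  pairs <- do.call(rbind, lapply(seq_len(k - 1), function(i) {
    do.call(rbind, lapply((i + 1):k, function(j) {
      fstat <- (mean[i] - mean[j])^2 / (msw * (1 / n[i] + 1 / n[j]))
      data.frame(group_i = labels[i], group_j = labels[j],
                 diff = mean[i] - mean[j], statistic = fstat,
                 critical = (k - 1) * fcrit,
                 significant = fstat > (k - 1) * fcrit,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(pairs) <- NULL
  ord <- order(mean)
  all_sig <- all(pairs$significant)
  ordering <- if (all_sig) {
    paste(labels[ord], collapse = " < ")
  } else if (any(pairs$significant)) {
    sig <- pairs[pairs$significant, , drop = FALSE]
    lo_first <- ifelse(sig$diff < 0,
                       paste(sig$group_i, "<", sig$group_j),
                       paste(sig$group_j, "<", sig$group_i))
    paste(lo_first, collapse = "; ")
  } else {
    "no significant pairs"
  }
  structure(list(pairs = pairs, ordering = ordering, alpha = alpha,
                 msw = msw),
            class = "scheffe_test")
}

#' @export
print.scheffe_test <- function(x, ...) {
  cat(sprintf("Scheffe post hoc comparisons (alpha = %g)\n", x$alpha))
  print(x$pairs, row.names = FALSE)
  cat("  ordering:", x$ordering, "\n")
  invisible(x)
}

#' Power of the ANCOVA/ANOVA group F-test
#'
#' Noncentral-F power with noncentrality `lambda = f^2 N` and denominator
#' degrees of freedom `N - k - c` (c covariates).
#'
#' @param effect_size_f Cohen's f.
#' @param n_total total sample size.
#' @param alpha significance level.
#' @param n_groups number of groups k.
#' @param n_covariates number of covariates c.
#' @return power in \[0, 1\] (0 when the denominator df is not positive).
#' @export
ancova_power <- function(effect_size_f, n_total, alpha = 0.05, n_groups,
                         n_covariates = 1) {
  df2 <- n_total - n_groups - n_covariates
  if (df2 < 1) return(0)
  df1 <- n_groups - 1
  crit <- stats::qf(1 - alpha, df1, df2)
  stats::pf(crit, df1, df2, ncp = effect_size_f^2 * n_total,
            lower.tail = FALSE)
}

#' Sample size for the covariate-adjusted group F-test
#'
#' Smallest total N whose noncentral-F power (see [ancova_power()]) reaches
#' the target, reported per group as `ceiling(N / k)`. The power function is
#' monotone increasing in N, so the search doubles an upper bound and then
#' bisects.
#'
#' @param effect_size_f Cohen's f (> 0).
#' @param alpha significance level in (0, 1).
#' @param power target power in (0, 1).
#' @param n_groups number of groups k.
#' @param n_covariates number of covariates c.
#' @param max_n iteration bound on total N.
#' @return list with `n_total`, `n_per_group`, `achieved_power`.
#' @export
#' @examples
#' ancova_sample_size(0.2, 0.05, 0.99, 3, 1)$n_per_group  # 180
ancova_sample_size <- function(effect_size_f, alpha = 0.05, power = 0.80,
                               n_groups, n_covariates = 1, max_n = 1e7) {
  assert_that(effect_size_f > 0, "effect size f must be positive")
  assert_that(alpha > 0 && alpha < 1, "alpha must be in (0, 1)")
  assert_that(power > 0 && power < 1, "power must be in (0, 1)")
  pow <- function(N) ancova_power(effect_size_f, N, alpha, n_groups,
                                  n_covariates)
  lo <- n_groups + n_covariates + 1  # minimal admissible N (df2 >= 1)
  if (pow(lo) >= power) {
    return(list(n_total = lo, n_per_group = ceiling(lo / n_groups),
                achieved_power = pow(lo)))
  }
  hi <- lo
  while (pow(hi) < power) {
    hi <- hi * 2
    if (hi > max_n) {
      stop("target power unreachable within iteration bound", call. = FALSE)
    }
  }
  while (hi - lo > 1) {
    mid <- (lo + hi) %/% 2
    if (pow(mid) >= power) hi <- mid else lo <- mid
  }
  list(n_total = hi, n_per_group = ceiling(hi / n_groups),
       achieved_power = pow(hi))
}

#' Inflate a per-group sample size for expected dropout
#'
#' `per_group = ceiling(n / (1 - dropout_rate))`; the total is the inflated
#' per-group size times the number of groups.
#'
#' @param n_per_group required completers per group.
#' @param dropout_rate expected dropout proportion in \[0, 1).
#' @param n_groups number of groups.
#' @return list with `n_per_group` (inflated) and `n_total`.
#' @export
#' @examples
#' inflate_for_dropout(180, 0.15, 3)  # 212 per group, 636 total
inflate_for_dropout <- function(n_per_group, dropout_rate, n_groups) {
  assert_that(dropout_rate >= 0 && dropout_rate < 1,
              "dropout_rate must be in [0, 1)")
  assert_that(n_per_group >= 1 && n_groups >= 1,
              "sample sizes must be positive")
  per <- ceiling(n_per_group / (1 - dropout_rate))
  list(n_per_group = per, n_total = per * n_groups)
}
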