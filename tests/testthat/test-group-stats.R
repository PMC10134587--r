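test_that("chi-square reproduces published 2x3 statistics without correction", {
  n <- c(206, 203, 198)
  compliance <- rbind(c(155, 191, 172), n - c(155, 191, 172))
  expect_equal(round_half_up(pearson_chi_square(compliance)$statistic, 2),
               29.57)
  tp <- rbind(c(63, 126, 98), n - c(63, 126, 98))
  expect_equal(round_half_up(pearson_chi_square(tp)$statistic, 2), 41.24)

  # identical row proportions -> exact independence
  expect_equal(pearson_chi_square(rbind(c(10, 20, 30), c(5, 10, 15)))$statistic,
               0)
  expect_error(pearson_chi_square(rbind(c(0, 0), c(1, 2))), "expected cell")
  expect_error(pearson_chi_square(matrix(1:3, 1)), "at least 2 x 2")
})

test_that("chi-square is permutation-invariant and matches stats::chisq.test", {
  t <- rbind(c(63, 126, 98), c(143, 77, 100))
  base <- pearson_chi_square(t)$statistic
  expect_equal(pearson_chi_square(t[, c(2, 3, 1)])$statistic, base)
  expect_equal(pearson_chi_square(t[2:1, ])$statistic, base)

  # oracle: every 2x2 table with cells 1..5, plus random 2x3 tables
  for (a in 1:5) for (b in 1:5) for (cc in 1:5) for (d in 1:5) {
    tab <- matrix(c(a, cc, b, d), 2)
    got <- pearson_chi_square(tab)
    ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-12)
  }
  set.seed(1)
  for (i in 1:50) {
    tab <- matrix(stats::rpois(6, 10) + 1, 2)
    got <- pearson_chi_square(tab)
    ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(got$p.value, unname(ref$p.value), tolerance = 1e-12)
  }
})

test_that("McNemar-Bowker handles 2x2, kxk and degenerate tables", {
  # b = 10, c = 2 discordant pairs
  expect_equal(mcnemar_bowker(matrix(c(20, 2, 10, 30), 2))$statistic, 64 / 12)
  expect_equal(mcnemar_bowker(matrix(c(20, 7, 7, 30), 2))$statistic, 0)

  sym <- matrix(c(5, 1, 2,
                  1, 6, 3,
                  2, 3, 7), 3, byrow = TRUE)
  r <- mcnemar_bowker(sym)
  expect_equal(r$statistic, 0)
  expect_equal(r$df, 3L)

  und <- mcnemar_bowker(diag(c(4, 5)))
  expect_true(is.na(und$statistic))
  expect_match(und$note, "undefined")
  expect_error(mcnemar_bowker(matrix(1:6, 2)), "square")

  # oracle: stats::mcnemar.test without correction on random tables
  set.seed(2)
  for (i in 1:25) {
    k <- sample(2:4, 1)
    tab <- matrix(stats::rpois(k * k, 6) + 1, k)
    got <- mcnemar_bowker(tab)
    ref <- stats::mcnemar.test(tab, correct = FALSE)
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(got$df, unname(ref$parameter))
  }
})

test_that("summary ANOVA equals raw-data ANOVA and the published F values", {
  age <- anova_from_summary(c(206, 203, 198), c(21.30, 21.59, 21.53),
                            c(1.44, 1.49, 2.00))
  expect_equal(age$statistic, 1.74, tolerance = 0.005)
  expect_equal(age$df, c(2, 604))

  expect_equal(anova_from_summary(c(10, 12), c(5, 5), c(1, 2))$statistic, 0)

  # moment-matching identity against stats::aov on raw data
  set.seed(3)
  for (i in 1:20) {
    k <- sample(2:5, 1)
    n <- sample(5:30, k, replace = TRUE)
    g <- factor(rep(seq_len(k), times = n))
    y <- stats::rnorm(sum(n), mean = as.integer(g))
    m <- tapply(y, g, mean)
    s <- tapply(y, g, sd)
    got <- anova_from_summary(n, as.vector(m), as.vector(s))
    ref <- summary(stats::aov(y ~ g))[[1]]
    expect_equal(got$statistic, ref[1, "F value"], tolerance = 1e-9)
    expect_equal(got$p.value, ref[1, "Pr(>F)"], tolerance = 1e-9)
  }
  expect_error(anova_from_summary(10, 5, 1), "at least 2")
})

test_that("ANCOVA reduces to ANOVA for a null, orthogonal covariate", {
  set.seed(4)
  n <- 45
  g <- factor(rep(1:3, each = n / 3))
  x <- stats::rnorm(n)
  x <- x - ave(x, g)  # exactly orthogonal to the group means
  y0 <- stats::rnorm(n)
  # remove the covariate component so the fitted slope is exactly zero
  y <- stats::residuals(stats::lm(y0 ~ x)) +
    c(0, 0.5, 1)[as.integer(g)]
  anc <- ancova_one_covariate(data.frame(group = g, covariate = x,
                                         outcome = y))
  av <- anova_from_summary(as.vector(table(g)),
                           as.vector(tapply(y, g, mean)),
                           as.vector(tapply(y, g, sd)))
  # identical sums of squares; only the denominator df differs (n-4 vs n-3)
  expect_equal(anc$statistic, av$statistic * (n - 4) / (n - 3),
               tolerance = 1e-9)
  expect_equal(anc$df, c(2, n - 4))
})

test_that("ANCOVA matches the Type III least-squares oracle", {
  skip_if_not_installed("car")
  set.seed(5)
  for (i in 1:10) {
    n <- sample(c(40, 61, 90), 1)
    g <- factor(sample(1:3, n, replace = TRUE))
    x <- stats::rnorm(n)
    y <- 0.6 * x + c(0, 0.4, 0.9)[as.integer(g)] + stats::rnorm(n)
    d <- data.frame(group = g, covariate = x, outcome = y)
    got <- ancova_one_covariate(d)
    old <- options(contrasts = c("contr.sum", "contr.poly"))
    ref <- car::Anova(stats::lm(outcome ~ covariate + group, data = d),
                      type = 3)
    options(old)
    expect_equal(got$statistic, ref["group", "F value"], tolerance = 1e-9)
    expect_equal(got$p.value, ref["group", "Pr(>F)"], tolerance = 1e-9)
  }
  expect_error(ancova_one_covariate(
    data.frame(group = c("a", "b"), covariate = c(1, 1), outcome = c(1, 2))),
    "covariate does not vary")
})

test_that("permuted outcomes put the ANCOVA F at its nominal critical value", {
  set.seed(6)
  n <- 45
  d <- data.frame(group = factor(rep(1:3, each = n / 3)),
                  covariate = stats::rnorm(n),
                  outcome = stats::rnorm(n))
  f_perm <- replicate(1000, {
    d$outcome <- sample(d$outcome)
    ancova_one_covariate(d)$statistic
  })
  crit <- stats::qf(0.95, 2, n - 4)
  emp <- unname(stats::quantile(f_perm, 0.95))
  expect_lt(abs(emp - crit) / crit, 0.2)
  expect_lt(abs(mean(f_perm > crit) - 0.05), 0.02)
})

test_that("Scheffe comparisons reproduce published orderings", {
  n <- c(206, 203, 198)
  # perceived ease of use: control lowest, then BADE, then CDV
  s <- scheffe_posthoc(n, c(1.03, 2.80, 2.47), c(1.36, 1.27, 1.27))
  expect_equal(s$ordering, "a < c < b")
  expect_true(all(s$pairs$significant))

  # completeness: interventions beat control, but do not separate
  s <- scheffe_posthoc(n, c(2.22, 3.04, 2.78), c(1.40, 1.32, 1.26))
  expect_equal(s$ordering, "a < b; a < c")

  s <- scheffe_posthoc(c(30, 30, 30), c(5, 5, 5), c(1, 1, 1))
  expect_equal(s$ordering, "no significant pairs")
})

test_that("two-group Scheffe equals the squared pooled t-test", {
  set.seed(7)
  n <- c(14, 19)
  m <- c(1.0, 1.8)
  s <- c(1.1, 0.9)
  sch <- scheffe_posthoc(n, m, s)
  msw <- sum((n - 1) * s^2) / (sum(n) - 2)
  t2 <- (m[1] - m[2])^2 / (msw * (1 / n[1] + 1 / n[2]))
  expect_equal(sch$pairs$statistic, t2, tolerance = 1e-12)
  # with k = 2 the Scheffe bound is 1 * F_crit = t_crit^2
  expect_equal(sch$pairs$critical,
               stats::qt(0.975, sum(n) - 2)^2, tolerance = 1e-9)
})

test_that("power is monotone and the sample-size search inverts it", {
  f <- 0.25
  pows <- sapply(c(60, 120, 240), function(N)
    ancova_power(f, N, n_groups = 3, n_covariates = 1))
  expect_true(all(diff(pows) > 0))
  expect_lt(ancova_power(0.1, 120, n_groups = 3, n_covariates = 1), pows[2])

  res <- ancova_sample_size(f, 0.05, 0.80, 3, 1)
  expect_gte(res$achieved_power, 0.80)
  # minimality: one fewer subject misses the target
  expect_lt(ancova_power(f, res$n_total - 1, 0.05, 3, 1), 0.80)

  # vanishing power target -> minimal admissible N (df positivity)
  tiny <- ancova_sample_size(0.5, 0.05, 1e-6, 3, 1)
  expect_equal(tiny$n_total, 5)

  # constant-power contour: doubling f about quarters N
  n1 <- ancova_sample_size(0.15, 0.05, 0.90, 3, 1)$n_total
  n2 <- ancova_sample_size(0.30, 0.05, 0.90, 3, 1)$n_total
  expect_lt(abs(n1 / n2 - 4), 0.4)
})

test_that("noncentral-F power agrees with Monte-Carlo rejection rates", {
  k <- 3; n_per <- 20; N <- k * n_per
  sigma <- 1
  d <- 0.5
  means <- c(-d, 0, d)
  f <- sqrt(sum((means - mean(means))^2) / k) / sigma
  set.seed(8)
  rej <- mean(replicate(600, {
    dd <- data.frame(group = factor(rep(1:k, each = n_per)),
                     covariate = stats::rnorm(N),
                     outcome = stats::rnorm(N, rep(means, each = n_per),
                                            sigma))
    ancova_one_covariate(dd)$p.value < 0.05
  }))
  expect_equal(rej, ancova_power(f, N, 0.05, k, 1), tolerance = 0.07)
})

test_that("dropout inflation reproduces the published sample sizes", {
  res <- inflate_for_dropout(180, 0.15, 3)
  expect_identical(res$n_per_group, 212)
  expect_identical(res$n_total, 636)
  expect_equal(inflate_for_dropout(100, 0, 3),
               list(n_per_group = 100, n_total = 300))
  expect_equal(inflate_for_dropout(85, 0.15, 1),
               list(n_per_group = 100, n_total = 100))
  expect_error(inflate_for_dropout(100, 1, 3), "dropout_rate")
})
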