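test_that("Welch t from raw data agrees with the summary route", {
  for (seed in 1:10) {
    set.seed(seed)
    x <- rnorm(20 + seed, 1, 2)
    y <- rnorm(35 - seed, 0.5, 1.2)
    raw <- welch_t(x, y)
    summ <- welch_t_from_summary(mean(x), sd(x), length(x),
                                 mean(y), sd(y), length(y))
    expect_equal(raw$t, summ$t, tolerance = 1e-12)
    expect_equal(raw$df, summ$df, tolerance = 1e-12)
    # cross-check against the stats implementation
    tt <- t.test(x, y)
    expect_equal(raw$t, unname(tt$statistic), tolerance = 1e-10)
    expect_equal(raw$df, unname(tt$parameter), tolerance = 1e-10)
    expect_equal(raw$p, tt$p.value, tolerance = 1e-10)
  }
  x <- rnorm(10)
  expect_equal(welch_t(x, x)$t, 0)
  # location shifts move t monotonically
  ts <- vapply(c(0, 0.5, 1, 2), function(d) welch_t(x, x + d)$t, numeric(1))
  expect_true(all(diff(ts) < 0))
})

test_that("Mann-Whitney U matches a brute-force pairwise count", {
  expect_equal(mann_whitney_u(1:5, 6:10)$U, 0)
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$U, 4.5)  # n1*n2/2
  for (seed in 1:10) {
    set.seed(seed)
    x <- sample(1:20, 12, replace = TRUE)  # ties on purpose
    y <- sample(1:20, 15, replace = TRUE)
    expect_equal(mann_whitney_u(x, y)$U, oracle_u_count(x, y))
  }
  # tie-free exact p agrees with wilcox.test
  set.seed(99)
  x <- rnorm(12); y <- rnorm(15) + 0.8
  got <- mann_whitney_u(x, y)
  ref <- wilcox.test(x, y, exact = TRUE)
  expect_equal(got$U, unname(ref$statistic))
  expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  # large tied samples: normal approximation against wilcox.test correct=FALSE
  set.seed(100)
  x <- sample(1:15, 60, replace = TRUE)
  y <- sample(3:18, 70, replace = TRUE)
  got2 <- mann_whitney_u(x, y)
  ref2 <- wilcox.test(x, y, exact = FALSE, correct = FALSE)
  expect_equal(got2$U, unname(ref2$statistic))
  expect_equal(got2$p, ref2$p.value, tolerance = 1e-8)
})

test_that("2x2 chi-square handles correction, independence and margins", {
  smoker <- matrix(c(42, 25, 20, 30), 2)  # rows HC/AUD, cols No/Yes
  expect_equal(chi2_2x2(smoker, continuity = TRUE)$X2,
               unname(chisq.test(smoker)$statistic), tolerance = 1e-10)
  expect_equal(chi2_2x2(smoker, continuity = FALSE)$X2,
               unname(chisq.test(smoker, correct = FALSE)$statistic),
               tolerance = 1e-10)
  # proportional rows -> exactly independent
  prop <- matrix(c(10, 20, 30, 60), 2)
  expect_equal(chi2_2x2(prop, continuity = FALSE)$X2, 0)
  expect_error(chi2_2x2(matrix(c(0, 0, 5, 7), 2)), "margin")
})

test_that("MAD mask flags gross outliers and respects affine maps", {
  m <- mad_outlier_mask(c(1, 2, 3, 4, 100))
  expect_identical(m, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_warning(mad_outlier_mask(rep(5, 6)), "MAD is zero")
  set.seed(1)
  x <- rnorm(50)
  expect_true(all(mad_outlier_mask(x) == mad_outlier_mask(3 * x - 7)))
  # symmetric tight data: nothing flagged
  expect_true(all(mad_outlier_mask(c(-2, -1, 0, 1, 2))))
})

test_that("standardization is idempotent and affine invariant", {
  expect_equal(standardize(c(0, 1)), c(-1, 1) / sqrt(2))
  set.seed(2)
  x <- rnorm(30, 5, 3)
  z <- standardize(x)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_equal(standardize(z), z, tolerance = 1e-12)
  expect_equal(standardize(2.5 * x + 11), z, tolerance = 1e-12)
  expect_error(standardize(rep(3, 5)), "zero variance")
})

test_that("normality screen separates normal from lognormal samples", {
  set.seed(3)
  ok <- normality_screen(rnorm(500))
  expect_true(ok$normal)
  skewed <- normality_screen(exp(rnorm(500)))
  expect_gt(skewed$skew_z, 3.29)
  expect_false(skewed$normal)
})

test_that("omega regression trims, standardizes and reports correctly", {
  set.seed(4)
  n <- 100
  group <- rep(c("HC", "AUD"), each = n / 2)
  d_cort <- rnorm(n, 0.3, 0.3)
  omega <- 0.6 - 0.1 * (group == "AUD") - 0.15 * d_cort + rnorm(n, 0, 0.1)
  ids <- sprintf("S%03d", seq_len(n))
  omega[7] <- 5          # gross outlier in omega
  d_cort[13] <- 4        # gross outlier in d_cort
  reg <- omega_interaction_regression(omega, group, d_cort, ids = ids)
  expect_setequal(reg$excluded, c("S007", "S013"))
  expect_equal(reg$n_used, 98L)
  expect_equal(reg$df2, reg$n_used - 4)
  expect_gte(reg$r_squared, 0)
  expect_lte(reg$r_squared, 1)
  expect_identical(reg$coefficients$term,
                   c("(Intercept)", "group", "d_cort", "group:d_cort"))

  # duplicating every subject leaves the coefficients unchanged up to
  # the n-1 sample-SD factor used in standardization (O(1/n) effect)
  reg2 <- omega_interaction_regression(rep(omega, 2), rep(group, 2),
                                       rep(d_cort, 2))
  expect_equal(reg2$coefficients$estimate, reg$coefficients$estimate,
               tolerance = 0.005)
  fit_dup <- lm(rep(standardize(omega[-c(7, 13)]), 2) ~
                  rep(group[-c(7, 13)] == "AUD", 2) *
                  rep(standardize(d_cort[-c(7, 13)]), 2))
  fit_one <- lm(standardize(omega[-c(7, 13)]) ~
                  (group[-c(7, 13)] == "AUD") *
                  standardize(d_cort[-c(7, 13)]))
  expect_equal(unname(coef(fit_dup)), unname(coef(fit_one)),
               tolerance = 1e-10)

  # an extra covariate enters as main effect plus d_cort interaction
  extra <- list(ospan = rnorm(n, 0.8, 0.15))
  reg3 <- omega_interaction_regression(omega, group, d_cort, extra = extra)
  expect_true(all(c("ospan", "d_cort:ospan") %in% reg3$coefficients$term))
})

test_that("null omega regressions keep nominal error and uniform p", {
  # light calibration check; the full 2000-replicate run lives in the
  # acceptance suite
  # trimming the response tails inflates the rate slightly (~0.055 at
  # this n), hence the band around the nominal level
  set.seed(5)
  ps <- replicate(800, {
    n <- 60
    g <- rep(c("HC", "AUD"), each = n / 2)
    reg <- omega_interaction_regression(rnorm(n), g, rnorm(n))
    reg$coefficients$p[4]
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.001)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.025)
})

test_that("Bayesian correlation behaves like a default Bayes factor", {
  set.seed(6)
  x <- rnorm(30)
  self <- bayes_pearson_cor(x, 2 * x + 1)
  expect_equal(self$r, 1)
  y <- rnorm(30)
  expect_equal(bayes_pearson_cor(x, y)$bf10, bayes_pearson_cor(y, x)$bf10,
               tolerance = 1e-8)
  # independent pairs at n = 48: evidence should typically favour the null
  bfs <- vapply(1:40, function(s) {
    set.seed(600 + s)
    bayes_pearson_cor(rnorm(48), rnorm(48))$bf10
  }, numeric(1))
  expect_lt(median(bfs), 1)
  # strong correlation at moderate n: decisive evidence
  expect_gt(bayes_pearson_cor(x, x + rnorm(30, 0, 0.4))$bf10, 10)
})

test_that("power analysis reproduces the standard t-test sample sizes", {
  expect_identical(power_n_per_group(0.5, 0.80, 0.05), 64L)
  expect_identical(power_n_per_group(0.8, 0.80, 0.05), 26L)
  # cross-check against stats::power.t.test at several effect sizes
  for (d in c(0.3, 0.5, 0.7, 1)) {
    ref <- ceiling(power.t.test(delta = d, power = 0.8,
                                sig.level = 0.05)$n)
    expect_equal(power_n_per_group(d, 0.8, 0.05), ref,
                 ignore_attr = TRUE)
  }
  ns <- vapply(c(0.2, 0.4, 0.6, 0.8), power_n_per_group, integer(1),
               power = 0.8, alpha = 0.05)
  expect_true(all(diff(ns) < 0))
})

test_that("change-score interaction equals the 2x2 mixed ANOVA F", {
  for (seed in 1:8) {
    set.seed(seed)
    n <- 24
    group <- rep(c("SECPT", "WPT"), each = n / 2)
    pre <- rnorm(n, 5, 2)
    post <- pre + ifelse(group == "SECPT", 0.8, 0) + rnorm(n, 0, 1)
    got <- change_score_interaction(pre, post, group)

    # explicit mixed-model ANOVA oracle on the long format
    long <- data.frame(
      y = c(pre, post),
      time = factor(rep(c("pre", "post"), each = n)),
      grp = factor(rep(group, 2)),
      id = factor(rep(seq_len(n), 2)))
    av <- summary(stats::aov(y ~ grp * time + Error(id), data = long))
    f_ref <- av[["Error: Within"]][[1]]["grp:time", "F value"]
    expect_equal(got$F, f_ref, tolerance = 1e-10)
    expect_equal(got$df2, n - 2)
  }
  same <- rnorm(10)
  expect_error(change_score_interaction(same, same, rep("A", 10)))
})
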