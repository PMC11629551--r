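#' Welch two-sample t-test from printed summary statistics
#'
#' Recomputes the unequal-variance t statistic and
#' Welch-Satterthwaite degrees of freedom from group means, SDs and
#' sizes, as needed to check published descriptive tables.
#'
#' @param mean1,sd1,n1 summary of the first group.
#' @param mean2,sd2,n2 summary of the second group.
#' @return List with `t` (`mean1 - mean2` in the numerator), `df`, `p`
#'   (two-sided).
#' @examples
#' welch_t_from_summary(6.58, 4.58, 62, 20.69, 5.1, 55)
#' @export
welch_t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(sd1 > 0 || sd2 > 0, n1 >= 2, n2 >= 2)
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  t <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Welch two-sample t-test from raw data
#'
#' @param x,y numeric vectors (length >= 2 each).
#' @return As [welch_t_from_summary()], applied to the vectors' own
#'   summaries.
#' @export
welch_t <- function(x, y) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (sd(x) == 0 && sd(y) == 0) stop_config("both samples have zero variance")
  welch_t_from_summary(mean(x), sd(x), length(x), mean(y), sd(y), length(y))
}

#' Mann-Whitney U test
#'
#' Reports U for the first sample (number of pairs with `x > y`, ties
#' counted half), so `U = 0` when every `x` is below every `y` and
#' `U = n1*n2/2` for identical multisets. The p-value is exact when
#' both samples are small and tie-free, otherwise a tie-corrected
#' normal approximation.
#'
#' @param x,y numeric vectors.
#' @return List with `U`, `p` (two-sided) and `method`.
#' @export
mann_whitney_u <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  stopifnot(n1 >= 1, n2 >= 1)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(c(x, y))
  has_ties <- any(ties > 1)
  n <- n1 + n2
  if (!has_ties && n1 <= 50 && n2 <= 50) {
    p <- 2 * min(stats::pwilcox(u, n1, n2),
                 stats::pwilcox(n1 * n2 - u, n1, n2))
    p <- min(1, p)
    method <- "exact"
  } else {
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma <- sqrt(n1 * n2 / 12 * ((n + 1) - tie_term))
    z <- (u - n1 * n2 / 2) / sigma
    p <- 2 * pnorm(-abs(z))
    method <- "normal approximation"
  }
  list(U = u, p = p, method = method)
}

#' Chi-square test on a 2x2 contingency table
#'
#' @param table 2x2 matrix of nonnegative counts with positive margins.
#' @param continuity apply the Yates continuity correction (default
#'   `TRUE`, matching the convention that reproduces printed 2x2
#'   statistics in clinical tables).
#' @return List with `X2`, `df = 1`, `p`.
#' @examples
#' chi2_2x2(matrix(c(42, 25, 20, 30), 2), continuity = TRUE)
#' @export
chi2_2x2 <- function(table, continuity = TRUE) {
  stopifnot(is.matrix(table), all(dim(table) == 2L), all(table >= 0))
  n <- sum(table)
  rs <- rowSums(table)
  cs <- colSums(table)
  if (any(rs == 0) || any(cs == 0)) stop_config("zero margin in 2x2 table")
  expected <- outer(rs, cs) / n
  d <- abs(table - expected)
  if (continuity) d <- pmax(0, d - 0.5)
  x2 <- sum(d^2 / expected)
  list(X2 = x2, df = 1L, p = pchisq(x2, 1, lower.tail = FALSE))
}

#' Median-absolute-deviation outlier mask
#'
#' Retains points within `k` scaled MADs of the median:
#' `|x - median| <= k * 1.4826 * median(|x - median|)`. The constant
#' 1.4826 makes the MAD a consistent estimator of the SD under
#' normality, following the usual robust-outlier literature.
#'
#' @param x numeric vector (length >= 3).
#' @param k cut-off in scaled MAD units (default 3).
#' @return Logical mask, `TRUE` for retained points. When the MAD is
#'   zero a warning is emitted and every point off the median is
#'   flagged.
#' @export
mad_outlier_mask <- function(x, k = 3) {
  stopifnot(length(x) >= 3)
  med <- median(x, na.rm = TRUE)
  raw_mad <- median(abs(x - med), na.rm = TRUE)
  if (is.na(raw_mad) || raw_mad == 0) {
    warning("MAD is zero; every point off the median is flagged")
    return(!is.na(x) & x == med)
  }
  !is.na(x) & abs(x - med) <= k * 1.4826 * raw_mad
}

#' Standardize a vector to mean 0, SD 1
#'
#' @param x numeric vector with positive sample SD (n-1 denominator).
#' @return The standardized vector.
#' @export
standardize <- function(x) {
  s <- sd(x, na.rm = TRUE)
  if (is.na(s) || s == 0) stop_config("cannot standardize: zero variance")
  (x - mean(x, na.rm = TRUE)) / s
}

#' Skewness/kurtosis normality screen
#'
#' Divides the bias-corrected sample skewness and excess kurtosis by
#' their small-sample standard errors; a distribution is treated as
#' normal when both standardized scores lie in the closed interval
#' \[-3.29, 3.29\] (the |z| < 0.001 two-sided criterion).
#'
#' @param x numeric vector (length >= 8).
#' @return List with `skew_z`, `kurt_z`, `normal`.
#' @export
normality_screen <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  stopifnot(n >= 8)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  g1 <- m3 / m2^1.5
  skew <- g1 * sqrt(n * (n - 1)) / (n - 2)
  g2 <- m4 / m2^2 - 3
  kurt <- ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
  se_skew <- sqrt(6 * n * (n - 1) / ((n - 2) * (n + 1) * (n + 3)))
  se_kurt <- 2 * se_skew * sqrt((n^2 - 1) / ((n - 3) * (n + 5)))
  skew_z <- skew / se_skew
  kurt_z <- kurt / se_kurt
  list(skew_z = skew_z, kurt_z = kurt_z,
       normal = abs(skew_z) <= 3.29 && abs(kurt_z) <= 3.29)
}

#' Regression of the model-based weight on group, cortisol increase and
#' their interaction
#'
#' Implements the full analysis pipeline for the headline test: (1)
#' MAD-based outlier trimming applied variable-wise to `omega` and
#' `d_cort` (and any continuous extra covariate) with union removal;
#' (2) standardization of the continuous variables on the retained
#' subjects; (3) OLS of standardized omega on group (HC = 0, AUD = 1),
#' standardized `d_cort`, and their product. A negative group
#' coefficient therefore means a lower model-based weight in the AUD
#' group.
#'
#' @param omega numeric vector of per-subject model-based weights.
#' @param group factor/character with levels `HC` and `AUD` (or a 0/1
#'   vector, 1 = AUD).
#' @param d_cort numeric vector of cortisol increases (log units).
#' @param extra optional named list of extra continuous covariates;
#'   each enters standardized as a main effect plus its interaction
#'   with `d_cort`.
#' @param mad_k MAD trimming constant (default 3).
#' @param ids optional subject identifiers for the exclusion report.
#' @return An `omega_regression` object: `coefficients` (estimate, SE,
#'   t, p per term), `F`, `df1`, `df2`, `p`, `r_squared`, `n_used`,
#'   `excluded` (ids of trimmed subjects).
#' @export
omega_interaction_regression <- function(omega, group, d_cort, extra = NULL,
                                         mad_k = 3, ids = NULL) {
  n <- length(omega)
  stopifnot(length(group) == n, length(d_cort) == n)
  ids <- ids %||% seq_len(n)
  g <- encode_group(group)
  keep <- mad_outlier_mask(omega, mad_k) & mad_outlier_mask(d_cort, mad_k)
  if (!is.null(extra)) {
    for (v in extra) keep <- keep & mad_outlier_mask(v, mad_k)
  }
  if (length(unique(g[keep])) < 2L) {
    stop_config("a group is absent after outlier trimming")
  }
  dat <- data.frame(omega = standardize(omega[keep]), group = g[keep],
                    d_cort = standardize(d_cort[keep]))
  form <- omega ~ group + d_cort + group:d_cort
  if (!is.null(extra)) {
    for (nm in names(extra)) {
      dat[[nm]] <- standardize(extra[[nm]][keep])
      form <- stats::update(form,
        stats::as.formula(sprintf("~ . + %s + %s:d_cort", nm, nm)))
    }
  }
  fit <- lm(form, data = dat)
  sm <- summary(fit)
  cf <- sm$coefficients
  out <- list(
    coefficients = data.frame(term = rownames(cf), estimate = cf[, 1],
                              se = cf[, 2], t = cf[, 3], p = cf[, 4],
                              row.names = NULL),
    F = unname(sm$fstatistic[1]), df1 = unname(sm$fstatistic[2]),
    df2 = unname(sm$fstatistic[3]),
    p = pf_overall(sm), r_squared = sm$r.squared,
    n_used = sum(keep), excluded = ids[!keep], lm_fit = fit)
  class(out) <- "omega_regression"
  out
}

pf_overall <- function(sm) {
  f <- sm$fstatistic
  stats::pf(f[1], f[2], f[3], lower.tail = FALSE)
}

encode_group <- function(group) {
  if (is.numeric(group)) {
    stopifnot(all(group %in% 0:1))
    return(as.numeric(group))
  }
  g <- as.character(group)
  stopifnot(all(g %in% c("HC", "AUD")))
  as.numeric(g == "AUD")
}

#' @export
print.omega_regression <- function(x, ...) {
  cat(sprintf(
    "omega ~ group * d_cort (standardized): F(%d, %d) = %.2f, p = %.3g, R2 = %.3f\n",
    x$df1, x$df2, x$F, x$p, x$r_squared))
  cat(sprintf("n used = %d (%d trimmed as MAD outliers)\n",
              x$n_used, length(x$excluded)))
  print(x$coefficients, digits = 3)
  invisible(x)
}

# Gauss hypergeometric 2F1 by series; converges for |z| < 1
hyp2f1 <- function(a, b, cc, z) {
  term <- 1
  s <- 1
  for (k in 0:100000) {
    term <- term * (a + k) * (b + k) / ((cc + k) * (k + 1)) * z
    s <- s + term
    if (abs(term) < 1e-15 * abs(s)) break
  }
  s
}

# Exact reduced likelihood of rho given (r, n) after integrating the
# bivariate-normal nuisance parameters (Ly-style closed form)
cor_reduced_lik <- function(rho, r, n) {
  even <- (1 - rho^2)^((n - 1) / 2) *
    hyp2f1((n - 1) / 2, (n - 1) / 2, 1 / 2, (rho * r)^2)
  odd <- 2 * rho * r * (1 - rho^2)^((n - 1) / 2) *
    exp(2 * (lgamma(n / 2) - lgamma((n - 1) / 2))) *
    hyp2f1(n / 2, n / 2, 3 / 2, (rho * r)^2)
  even + odd
}

#' Bayesian Pearson correlation with a default Bayes factor
#'
#' Computes the sample Pearson correlation and the two-sided Bayes
#' factor for a nonzero correlation under the default stretched-beta
#' prior on rho (width `kappa = 1`, i.e. uniform on \[-1, 1\]),
#' obtained by numerical integration of the reduced likelihood of rho
#' given `(r, n)`.
#'
#' @param x,y numeric vectors (n >= 4, positive variance).
#' @param kappa prior width of the stretched beta (default 1).
#' @return A `bayes_cor` list: `r`, `n`, `bf10`.
#' @export
bayes_pearson_cor <- function(x, y, kappa = 1) {
  keep <- complete.cases(x, y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  stopifnot(n >= 4)
  if (sd(x) == 0 || sd(y) == 0) stop_config("zero variance input")
  r <- stats::cor(x, y)
  if (abs(r) >= 1 - 1e-10) {
    # a perfect sample correlation carries unbounded evidence
    return(structure(list(r = r, n = n, bf10 = Inf), class = "bayes_cor"))
  }
  num <- integrate(function(rho) {
    vapply(rho, cor_reduced_lik, numeric(1), r = r, n = n) *
      dbeta((rho + 1) / 2, 1 / kappa, 1 / kappa) / 2
  }, -1, 1, rel.tol = 1e-10)$value
  bf10 <- num / cor_reduced_lik(0, r, n)
  structure(list(r = r, n = n, bf10 = bf10), class = "bayes_cor")
}

#' @export
print.bayes_cor <- function(x, ...) {
  cat(sprintf("Pearson r(%d) = %.3f, BF10 = %.3g\n", x$n - 2, x$r, x$bf10))
  invisible(x)
}

#' Per-group sample size for a two-sample t-test
#'
#' Smallest per-group n giving the target power for a two-sided
#' two-sample t-test at standardized effect size `effect_d`, by direct
#' evaluation of the noncentral-t power curve.
#'
#' @param effect_d standardized mean difference (Cohen's d).
#' @param power target power (default 0.80).
#' @param alpha two-sided significance level (default 0.05).
#' @return Integer per-group sample size.
#' @examples
#' power_n_per_group(0.5)  # 64
#' @export
power_n_per_group <- function(effect_d, power = 0.80, alpha = 0.05) {
  stopifnot(effect_d > 0, power > 0, power < 1, alpha > 0, alpha < 1)
  power_at <- function(n) {
    df <- 2 * n - 2
    ncp <- effect_d * sqrt(n / 2)
    crit <- qt(1 - alpha / 2, df)
    pt(crit, df, ncp, lower.tail = FALSE) + pt(-crit, df, ncp)
  }
  n <- 2
  while (power_at(n) < power) n <- n + 1
  as.integer(n)
}

#' Group x time interaction on change scores
#'
#' Two-sample pooled-variance t-test on `post - pre` between groups,
#' reported as `F = t^2` with `(1, n - 2)` degrees of freedom — the
#' exact interaction test of the 2 (group) x 2 (time) mixed design.
#'
#' @param pre,post aligned numeric vectors.
#' @param group two-level grouping vector.
#' @return List with `F`, `df1 = 1`, `df2`, `p`.
#' @export
change_score_interaction <- function(pre, post, group) {
  stopifnot(length(pre) == length(post), length(group) == length(pre))
  d <- post - pre
  g <- as.factor(group)
  stopifnot(nlevels(g) == 2L)
  n1 <- sum(g == levels(g)[1])
  n2 <- sum(g == levels(g)[2])
  if (n1 < 2 || n2 < 2) stop_config("each group needs >= 2 subjects")
  d1 <- d[g == levels(g)[1]]
  d2 <- d[g == levels(g)[2]]
  sp2 <- ((n1 - 1) * var(d1) + (n2 - 1) * var(d2)) / (n1 + n2 - 2)
  t <- (mean(d1) - mean(d2)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  f <- t^2
  df2 <- n1 + n2 - 2
  list(F = f, df1 = 1L, df2 = df2, p = stats::pf(f, 1, df2, lower.tail = FALSE))
}
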