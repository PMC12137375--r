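#' Convergent-validity correlation table with Bonferroni correction
#'
#' Pearson correlations between all pairs of task-score columns, with
#' two-sided p values and Bonferroni-adjusted p values. The default family
#' size is 10, the number of pairwise correlations among five tasks.
#'
#' @param scores Data.frame or matrix of per-participant task scores, one
#'   column per task.
#' @param family_size Number of tests in the Bonferroni family; defaults to
#'   the number of column pairs.
#' @return A data.frame of class `correlation_table` with columns `task1`,
#'   `task2`, `r`, `p_raw`, `p_adjusted`, `n`.
#' @export
correlation_matrix <- function(scores, family_size = NULL) {
  scores <- as.data.frame(scores)
  if (ncol(scores) < 2) stop("need at least two score columns")
  nm <- names(scores)
  pairs <- utils::combn(nm, 2, simplify = FALSE)
  m <- if (is.null(family_size)) length(pairs) else family_size
  rows <- lapply(pairs, function(p) {
    x <- scores[[p[1]]]; y <- scores[[p[2]]]
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 4) stop("fewer than 4 complete pairs for ", p[1], "-", p[2])
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
      stop("zero-variance column: ", p[1], " or ", p[2])
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
    data.frame(task1 = p[1], task2 = p[2], r = unname(ct$estimate),
               p_raw = ct$p.value, p_adjusted = min(1, m * ct$p.value),
               n = sum(ok), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "family_size") <- m
  class(out) <- c("correlation_table", "data.frame")
  out
}

#' Two-way random-effects intraclass correlation
#'
#' Single-rater intraclass correlation from a two-way random-effects ANOVA
#' over participants (rows) and sessions (columns). The default `"agreement"`
#' form is ICC(2,1) in the Shrout--Fleiss convention,
#' \deqn{(MS_R - MS_E) / (MS_R + (k-1) MS_E + k (MS_C - MS_E)/n),}
#' which counts session mean differences against agreement; the
#' `"consistency"` form ICC(3,1) ignores them. Confidence bounds come from
#' the corresponding F-distribution limits (McGraw--Wong).
#'
#' @param s1,s2 Paired score vectors from the two sessions.
#' @param type `"agreement"` (default) or `"consistency"`.
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return A list of class `icc_result`: `icc`, `ci_low`, `ci_high`,
#'   `ms_rows`, `ms_cols`, `ms_error`, `n`, `k`, `type`, `conf_level`.
#' @examples
#' set.seed(1)
#' s1 <- rnorm(50, 5, 1.4); s2 <- 0.8 * s1 + rnorm(50, 1, 0.9)
#' icc_two_way_random(s1, s2)
#' @export
icc_two_way_random <- function(s1, s2, type = c("agreement", "consistency"),
                               conf_level = 0.95) {
  type <- match.arg(type)
  s1 <- as.numeric(s1); s2 <- as.numeric(s2)
  if (length(s1) != length(s2)) stop("`s1` and `s2` must be the same length")
  ok <- stats::complete.cases(s1, s2)
  s1 <- s1[ok]; s2 <- s2[ok]
  n <- length(s1); k <- 2L
  if (n < 5) stop("need at least 5 paired scores")
  dat <- cbind(s1, s2)
  grand <- mean(dat)
  row_means <- rowMeans(dat)
  col_means <- colMeans(dat)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_tot <- sum((dat - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  if (msr <= 0 && mse <= 0) stop("degenerate variance: all scores equal")
  alpha <- 1 - conf_level
  if (type == "agreement") {
    icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
    # McGraw & Wong (1996) CI for ICC(A,1)
    a <- (k * icc) / (n * (1 - icc))
    b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f_low <- stats::qf(1 - alpha / 2, n - 1, v)
    f_up <- stats::qf(1 - alpha / 2, v, n - 1)
    ci_low <- n * (msr - f_low * mse) /
      (f_low * (k * msc + (k * n - k - n) * mse) + n * msr)
    ci_high <- n * (f_up * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_up * msr)
  } else {
    icc <- (msr - mse) / (msr + (k - 1) * mse)
    fobs <- msr / mse
    f_low <- stats::qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
    f_up <- stats::qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
    ci_low <- (fobs / f_low - 1) / (fobs / f_low + k - 1)
    ci_high <- (fobs * f_up - 1) / (fobs * f_up + k - 1)
  }
  structure(list(icc = icc, ci_low = ci_low, ci_high = ci_high,
                 ms_rows = msr, ms_cols = msc, ms_error = mse,
                 n = n, k = k, type = type, conf_level = conf_level),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC (%s, single rater, two-way random): %.3f, %d%% CI [%.3f, %.3f], n = %d\n",
              x$type, x$icc, round(100 * x$conf_level), x$ci_low, x$ci_high,
              x$n))
  invisible(x)
}

# Gauss hypergeometric 2F1 by power series; converges for |z| < 1, which
# holds here since z = (1 + rho * r) / 2 with |rho|, |r| < 1.
hyp2f1_series <- function(a, b, cc, z, tol = 1e-15, maxit = 100000L) {
  term <- 1; s <- 1
  for (k in 0:(maxit - 1)) {
    term <- term * (a + k) * (b + k) / ((cc + k) * (k + 1)) * z
    s <- s + term
    if (abs(term) < tol * abs(s)) return(s)
  }
  stop("2F1 series did not converge")
}

# log-likelihood of the population correlation rho given the observed sample
# correlation r at sample size n, up to terms constant in rho (the exact
# sampling density of r under bivariate normality)
log_lik_rho <- function(rho, r, n) {
  (n - 1) / 2 * log1p(-rho^2) - (n - 1.5) * log1p(-rho * r) +
    log(hyp2f1_series(0.5, 0.5, (2 * n - 1) / 2, (1 + rho * r) / 2))
}

#' Bayes factor for a Pearson correlation under a stretched beta prior
#'
#' Two-sided Bayes factor BF10 (alternative over null) for a correlation
#' test, with the population correlation given a "stretched" beta prior on
#' (-1, 1): rho = 2x - 1 with x ~ Beta(1/kappa, 1/kappa). Width `kappa = 1`
#' is the default (uniform) prior. The marginal likelihood is obtained by
#' numerical integration of the exact sampling density of the sample
#' correlation over the prior.
#'
#' @param r Observed Pearson correlation, `|r| < 1`.
#' @param n Number of pairs, at least 4.
#' @param kappa Prior width, positive (default 1).
#' @return A list of class `bf_result`: `bf10`, `r`, `n`, `kappa`.
#' @examples
#' bayes_cor_bf10(0.05, 207)  # strong evidence for the null: about 0.11
#' @export
bayes_cor_bf10 <- function(r, n, kappa = 1) {
  if (!is.finite(r) || abs(r) >= 1) stop("`r` must satisfy |r| < 1")
  n <- as.integer(n)
  if (n < 4) stop("`n` must be at least 4")
  if (!is.finite(kappa) || kappa <= 0) stop("`kappa` must be positive")
  a <- 1 / kappa
  ll0 <- log_lik_rho(0, r, n)
  log_prior_const <- -(2 * a - 1) * log(2) - lbeta(a, a)
  integrand <- function(rho) {
    lr <- vapply(rho, log_lik_rho, numeric(1), r = r, n = n)
    exp(lr - ll0 + log_prior_const + (a - 1) * log1p(-rho^2))
  }
  bf <- stats::integrate(integrand, -1, 1, rel.tol = 1e-10,
                         subdivisions = 500L)$value
  structure(list(bf10 = bf, r = r, n = n, kappa = kappa),
            class = "bf_result")
}

#' @export
print.bf_result <- function(x, ...) {
  cat(sprintf("BF10 = %.4g  (r = %.3f, n = %d, prior width %.2f)\n",
              x$bf10, x$r, x$n, x$kappa))
  invisible(x)
}

#' Analytic power for a Pearson correlation test
#'
#' Power of the significance test of a correlation via the Fisher z
#' approximation: with effect `z_e = |atanh(rho)| * sqrt(n - 3)` and critical
#' value `z_c` at `alpha / sides`, the one-sided power is
#' `pnorm(z_e - z_c)`; the two-sided power adds the opposite rejection tail
#' `pnorm(-z_e - z_c)`, which makes the test exactly size alpha at rho = 0
#' and is negligible for any non-trivial effect.
#'
#' @param rho True (population) correlation.
#' @param n Sample size, at least 4.
#' @param alpha Significance level (default 0.05).
#' @param sides 2 (default) for a two-sided test, 1 for one-sided.
#' @return Power as a probability.
#' @examples
#' correlation_power(0.20, 250)  # about 0.89
#' @export
correlation_power <- function(rho, n, alpha = 0.05, sides = 2) {
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)")
  if (!sides %in% c(1, 2)) stop("`sides` must be 1 or 2")
  if (any(n < 4)) stop("`n` must be at least 4")
  if (abs(rho) >= 1) stop("`rho` must satisfy |rho| < 1")
  zc <- stats::qnorm(1 - alpha / sides)
  ze <- abs(atanh(rho)) * sqrt(n - 3)
  if (sides == 1) stats::pnorm(ze - zc)
  else stats::pnorm(ze - zc) + stats::pnorm(-ze - zc)
}

#' Smallest sample size reaching a target correlation power
#'
#' Inverts [correlation_power()]: the smallest integer n at which the Fisher
#' z power reaches `power`.
#'
#' @inheritParams correlation_power
#' @param power Target power in (alpha, 1).
#' @return Integer sample size.
#' @examples
#' required_n(0.20, 0.90)  # about 258 under the Fisher z approximation
#' @export
required_n <- function(rho, power, alpha = 0.05, sides = 2) {
  if (rho == 0) stop("power beyond alpha is unattainable at rho = 0")
  if (power <= alpha || power >= 1) stop("`power` must be in (alpha, 1)")
  zc <- stats::qnorm(1 - alpha / sides)
  zp <- stats::qnorm(power)
  n0 <- max(4, floor(((zc + zp) / abs(atanh(rho)))^2 + 3))
  n <- n0
  while (correlation_power(rho, n, alpha, sides) < power) n <- n + 1
  while (n > 4 && correlation_power(rho, n - 1, alpha, sides) >= power)
    n <- n - 1
  as.integer(n)
}

#' Flag retest outliers by mean absolute deviation of score differences
#'
#' Computes the session-score differences d = s1 - s2 and flags participants
#' whose difference lies more than `threshold` mean absolute deviations from
#' the mean difference: `|d - mean(d)| > threshold * mean(|d - mean(d)|)`.
#'
#' @param s1,s2 Paired score vectors.
#' @param threshold Number of mean absolute deviations (default 5).
#' @return Logical vector, `TRUE` for flagged participants.
#' @export
flag_retest_outliers <- function(s1, s2, threshold = 5) {
  s1 <- as.numeric(s1); s2 <- as.numeric(s2)
  if (length(s1) != length(s2)) stop("`s1` and `s2` must be the same length")
  if (length(s1) < 2) stop("need at least 2 paired scores")
  d <- s1 - s2
  dev <- abs(d - mean(d))
  mad_mean <- mean(dev)
  dev > threshold * mad_mean
}
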