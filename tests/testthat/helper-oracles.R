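# Independent oracles used across the suite. Each is coded as a separate
# route from the implementation it checks.

# Brute-force span scorer working directly on (level, passed) trial vectors:
# scans levels from the top for the highest passed at least twice, then
# counts passed trials strictly above it.
oracle_span_score <- function(levels, passed) {
  base <- 0
  for (lv in sort(unique(levels), decreasing = TRUE)) {
    n_pass <- 0
    for (i in seq_along(levels))
      if (levels[i] == lv && passed[i]) n_pass <- n_pass + 1
    if (n_pass >= 2) { base <- lv; break }
  }
  partial <- 0
  for (i in seq_along(levels))
    if (passed[i] && levels[i] > base) partial <- partial + 0.5
  list(base = base, partial = partial, final = base + partial)
}

# Two-way ANOVA ICC oracle via aov(): mean squares from R's ANOVA table
# rather than hand-accumulated sums of squares.
oracle_icc_agreement <- function(s1, s2) {
  n <- length(s1); k <- 2
  long <- data.frame(score = c(s1, s2),
                     subj = factor(rep(seq_len(n), 2)),
                     sess = factor(rep(1:2, each = n)))
  ms <- summary(stats::aov(score ~ subj + sess, data = long))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# Exact-formula Bayes factors for the stretched-beta (kappa = 1) prior,
# frozen from pingouin.bayesfactor_pearson (Ly et al. closed form).
oracle_bf10 <- data.frame(
  r = c(0.05, 0, 0.5, 0.5, 0.3, -0.2),
  n = c(207L, 10L, 100L, 50L, 40L, 80L),
  bf10 = c(0.11217958870070757, 0.3865631585471815, 125565.3887729837,
           134.76165071716477, 1.0859066357170388, 0.6603985043380834)
)

# Monte-Carlo power of the Pearson correlation t test, vectorized over
# replications (simulate bivariate normal, test via the t transform of r).
oracle_power_mc <- function(rho, n, alpha = 0.05, reps = 40000L) {
  x <- matrix(stats::rnorm(reps * n), n, reps)
  y <- rho * x + sqrt(1 - rho^2) * matrix(stats::rnorm(reps * n), n, reps)
  cx <- sweep(x, 2, colMeans(x)); cy <- sweep(y, 2, colMeans(y))
  r <- colSums(cx * cy) / sqrt(colSums(cx^2) * colSums(cy^2))
  tstat <- r * sqrt(n - 2) / sqrt(1 - r^2)
  mean(abs(tstat) > stats::qt(1 - alpha / 2, n - 2))
}

# Small deterministic staircase responders.
responder_always <- function(flag) function(level) flag
# alternates over the *test* trials (the first call a session makes is the
# practice trial, which is passed and excluded from scoring)
responder_alternating <- function(first = TRUE) {
  calls <- 0
  function(level) {
    calls <<- calls + 1
    if (calls == 1) TRUE
    else if (calls %% 2 == 0) first
    else !first
  }
}
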