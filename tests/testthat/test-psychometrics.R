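test_that("correlation table reports Pearson r with capped Bonferroni adjustment", {
  set.seed(3)
  x <- rnorm(60)
  scores <- data.frame(a = x, b = x, c = rnorm(60))
  tab <- correlation_matrix(scores)
  expect_equal(tab$r[tab$task1 == "a" & tab$task2 == "b"], 1)
  expect_equal(tab$p_adjusted, pmin(1, attr(tab, "family_size") * tab$p_raw))
  expect_true(all(tab$p_adjusted >= tab$p_raw))
  # family size is configurable: p 0.004 with m = 10 adjusts to 0.04
  expect_equal(min(1, 10 * 0.004), 0.04)
  tab10 <- correlation_matrix(data.frame(a = rnorm(30), b = rnorm(30)),
                              family_size = 10)
  expect_equal(tab10$p_adjusted, pmin(1, 10 * tab10$p_raw))
  expect_error(correlation_matrix(data.frame(a = rnorm(10), b = rep(1, 10))),
               "zero-variance")
})

test_that("independent columns show near-zero correlation at large n", {
  set.seed(4)
  scores <- data.frame(a = rnorm(2000), b = rnorm(2000))
  expect_lt(abs(correlation_matrix(scores)$r), 0.06)
})

test_that("agreement ICC matches the aov oracle and is 1 for identical sessions", {
  s1 <- c(1, 2, 3, 4, 5, 6)
  s2 <- c(2, 1, 3, 5, 4, 6)
  got <- icc_two_way_random(s1, s2)
  expect_equal(got$icc, oracle_icc_agreement(s1, s2), tolerance = 1e-10)
  expect_true(got$ci_low <= got$icc && got$icc <= got$ci_high)
  ident <- icc_two_way_random(s1, s1)
  expect_equal(ident$icc, 1)
  set.seed(5)
  a <- rnorm(40, 5, 1.4); b <- 0.7 * a + rnorm(40, 1.5, 1)
  expect_equal(icc_two_way_random(a, b)$icc, oracle_icc_agreement(a, b),
               tolerance = 1e-10)
})

test_that("ICC is near zero for independent sessions and near Pearson r when calibrated", {
  set.seed(6)
  ind <- icc_two_way_random(rnorm(2000), rnorm(2000))
  expect_lt(abs(ind$icc), 0.05)
  # equal session means and variances: agreement ICC approaches Pearson r
  z <- rnorm(3000)
  s1 <- 5 + z
  s2 <- 5 + 0.75 * z + sqrt(1 - 0.75^2) * rnorm(3000)
  fit <- icc_two_way_random(s1, s2)
  expect_equal(fit$icc, cor(s1, s2), tolerance = 0.01)
  # consistency form ignores a constant session shift, agreement does not
  sh <- icc_two_way_random(s1, s2 + 2)
  expect_lt(sh$icc, fit$icc - 0.2)
  expect_equal(icc_two_way_random(s1, s2 + 2, type = "consistency")$icc,
               icc_two_way_random(s1, s2, type = "consistency")$icc,
               tolerance = 1e-10)
})

test_that("correlation Bayes factor matches the exact-formula oracle", {
  for (i in seq_len(nrow(oracle_bf10))) {
    got <- bayes_cor_bf10(oracle_bf10$r[i], oracle_bf10$n[i])
    expect_equal(got$bf10, oracle_bf10$bf10[i], tolerance = 1e-4)
  }
})

test_that("Bayes factor behaves like evidence", {
  # increasing in |r| at fixed n
  bfs <- vapply(c(0, 0.1, 0.2, 0.3, 0.4),
                function(r) bayes_cor_bf10(r, 60)$bf10, numeric(1))
  expect_true(all(diff(bfs) > 0))
  # at r = 0, evidence for the null accumulates with n
  nulls <- vapply(c(10, 50, 200, 1000),
                  function(n) bayes_cor_bf10(0, n)$bf10, numeric(1))
  expect_true(all(diff(nulls) < 0))
  expect_lt(bayes_cor_bf10(0, 10)$bf10, 1)
  # more data at fixed nonzero r means more evidence for the alternative
  expect_gt(bayes_cor_bf10(0.5, 100)$bf10, bayes_cor_bf10(0.5, 50)$bf10)
  # Jeffreys' asymptotic approximation within 5% for n >= 100
  for (case in list(c(0.05, 207), c(0.1, 150), c(0.15, 100))) {
    r <- case[1]; n <- case[2]
    jeffreys <- sqrt(pi / (2 * n - 3)) * (1 - r^2)^(-(n - 4) / 2)
    expect_equal(bayes_cor_bf10(r, n)$bf10, jeffreys, tolerance = 0.05)
  }
  expect_error(bayes_cor_bf10(1, 50), "\\|r\\|")
  expect_error(bayes_cor_bf10(0.2, 50, kappa = 0), "kappa")
})

test_that("analytic correlation power matches the Monte-Carlo oracle on a 3x3 grid", {
  set.seed(7)
  for (rho in c(0.1, 0.2, 0.3)) {
    for (n in c(60, 120, 250)) {
      expect_equal(correlation_power(rho, n),
                   oracle_power_mc(rho, n, reps = 60000L),
                   tolerance = 0.01)
    }
  }
})

test_that("power is a size-alpha, monotone function inverted by required_n", {
  expect_equal(correlation_power(0, 100), 0.05, tolerance = 1e-12)
  expect_equal(correlation_power(0, 100, alpha = 0.01), 0.01,
               tolerance = 1e-12)
  grid_n <- vapply(c(50, 100, 200), function(n) correlation_power(0.2, n),
                   numeric(1))
  expect_true(all(diff(grid_n) > 0))
  grid_r <- vapply(c(0.1, 0.2, 0.3), function(r) correlation_power(r, 100),
                   numeric(1))
  expect_true(all(diff(grid_r) > 0))
  n90 <- required_n(0.2, 0.9)
  expect_gte(correlation_power(0.2, n90), 0.9)
  expect_lt(correlation_power(0.2, n90 - 1), 0.9)
  expect_error(required_n(0, 0.9), "rho")
})

test_that("retest outlier flags follow the mean-absolute-deviation rule", {
  expect_false(any(flag_retest_outliers(1:10, 1:10)))
  # d = (0 x19, 20): mean 1, mean |d - mean| = 1.9, deviation 19 > 9.5
  s1 <- c(rep(0, 19), 20); s2 <- rep(0, 20)
  flags <- flag_retest_outliers(s1, s2)
  expect_identical(which(flags), 20L)
  expect_false(any(flag_retest_outliers(s1, s2, threshold = Inf)))
  # scale equivariance
  expect_identical(flag_retest_outliers(3 * s1, 3 * s2), flags)
  expect_error(flag_retest_outliers(1, 1), "at least 2")
})
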