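test_that("composite standardization uses the sample-SD convention", {
  expect_equal(standardize_composite(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(41)
  z <- standardize_composite(runif(50, 0, 100))
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_error(standardize_composite(rep(2, 10)), "zero variance")
  expect_error(standardize_composite(1), "at least 2")
})

test_that("with zero random-effect variance the GLMM matches plain grouped logistic regression", {
  set.seed(42)
  span <- rnorm(120, 5, 1.4)
  age <- runif(120, 18, 65)
  counts <- simulate_transcription_counts(
    span, age, n_items = 10, coefs = c(0.2, 0.3, -0.02, 0),
    sigma_subject = 0, sigma_item = 0)
  fit <- fit_grouped_binomial_glmm(counts)
  ref <- glm(cbind(n_correct, n_missed) ~ span_score + age +
               span_score:age, family = binomial, data = counts)
  eta_glmm <- as.matrix(cbind(1, counts$span_score, counts$age,
                              counts$span_score * counts$age)) %*%
    fit$coefficients$estimate
  expect_lt(max(abs(eta_glmm - predict(ref, type = "link"))), 1e-3)
})

test_that("a flat pooled dataset recovers the logit of pooled accuracy", {
  set.seed(43)
  counts <- simulate_transcription_counts(
    rep(5, 50), rep(40, 50), n_items = 8, coefs = c(0.4, 0, 0, 0),
    sigma_subject = 0, sigma_item = 0)
  fit <- fit_grouped_binomial_glmm(counts, fixed = character(0))
  pooled <- sum(counts$n_correct) / sum(counts$n_correct + counts$n_missed)
  expect_equal(fit$coefficients$estimate[1], qlogis(pooled),
               tolerance = 1e-2)
  expect_error(fit_grouped_binomial_glmm(counts[1, ]), "at least 2")
})

test_that("the grouped-binomial fit is invariant to row order and row splitting", {
  set.seed(44)
  span <- rnorm(40, 5, 1.4)
  counts <- simulate_transcription_counts(
    span, runif(40, 18, 65), n_items = 6, coefs = c(0, 0.25, 0, 0))
  fit <- fit_grouped_binomial_glmm(counts, fixed = "span")
  perm <- counts[sample(nrow(counts)), ]
  fit_perm <- fit_grouped_binomial_glmm(perm, fixed = "span")
  expect_equal(fit$coefficients$estimate, fit_perm$coefficients$estimate,
               tolerance = 1e-5)
  expect_equal(fit$loglik, fit_perm$loglik, tolerance = 1e-6)
  # split each row into two half-rows with the same covariates
  lo <- counts; hi <- counts
  lo$n_correct <- counts$n_correct %/% 2
  lo$n_missed <- counts$n_missed %/% 2
  hi$n_correct <- counts$n_correct - lo$n_correct
  hi$n_missed <- counts$n_missed - lo$n_missed
  fit_split <- fit_grouped_binomial_glmm(rbind(lo, hi), fixed = "span")
  expect_equal(fit$coefficients$estimate, fit_split$coefficients$estimate,
               tolerance = 1e-4)
})

test_that("likelihood-ratio tests count fixed-effect df and stay non-negative", {
  set.seed(45)
  counts <- simulate_transcription_counts(
    rnorm(60, 5, 1.4), runif(60, 18, 65), n_items = 8,
    coefs = c(0, 0.3, -0.02, 0))
  full <- fit_grouped_binomial_glmm(counts)
  no_int <- fit_grouped_binomial_glmm(counts, fixed = c("span", "age"))
  none <- fit_grouped_binomial_glmm(counts, fixed = character(0))
  self <- likelihood_ratio_test(full, full)
  expect_equal(self$chi2, 0)
  expect_equal(self$p, 1)
  lrt <- likelihood_ratio_test(full, no_int)
  expect_equal(lrt$df, 1L)
  expect_gte(lrt$chi2, 0)
  expect_equal(likelihood_ratio_test(full, none)$df, 3L)
  expect_error(likelihood_ratio_test(none, full), "more fixed effects")
})

test_that("ratings model recovers injected task shifts at the published magnitudes", {
  set.seed(46)
  n <- 250
  shifts <- c(digit_aud = -0.35, digit_vis = -0.42, free_aud = -0.39,
              free_vis = -0.45)
  tasks <- c("sandwich", names(shifts))
  # average the recovered contrasts over replicate cohorts so the check on
  # the +-0.1 recovery band is not dominated by single-draw noise
  reps <- lapply(1:10, function(rep) {
    dat <- expand.grid(participant = sprintf("P%03d", 1:n), task = tasks,
                       stringsAsFactors = FALSE)
    u <- setNames(rnorm(n, 0, 0.5), sprintf("P%03d", 1:n))
    cb <- setNames(sample(rep(1:5, n / 5)), sprintf("P%03d", 1:n))
    dat$counterbalance <- cb[dat$participant]
    dat$composite <- ifelse(dat$task == "sandwich", 0, shifts[dat$task]) +
      u[dat$participant] + rnorm(nrow(dat), 0, 0.8)
    dat
  })
  fits <- lapply(reps, fit_ratings_lmm)
  recovered <- rowMeans(sapply(fits, function(f)
    f$task_contrasts[names(shifts)]))
  expect_equal(unname(recovered), unname(shifts), tolerance = 0.1)
  lrt <- ratings_task_lrt(reps[[1]])
  expect_equal(lrt$df, 4L)
  expect_lt(lrt$p, 0.001)
})

test_that("participant-only variation yields zero task contrasts", {
  n <- 30
  tasks <- c("sandwich", "digit_aud", "digit_vis", "free_aud", "free_vis")
  dat <- expand.grid(participant = sprintf("P%02d", 1:n), task = tasks,
                     stringsAsFactors = FALSE)
  u <- setNames(seq(-1, 1, length.out = n), sprintf("P%02d", 1:n))
  dat$counterbalance <- rep(1:5, length.out = nrow(dat))
  dat$composite <- u[dat$participant]
  fit <- fit_ratings_lmm(dat)
  expect_equal(unname(fit$task_contrasts), rep(0, 4), tolerance = 1e-6)
})

test_that("the ratings task LRT is calibrated under the null", {
  set.seed(47)
  n <- 40
  tasks <- c("sandwich", "digit_aud", "digit_vis", "free_aud", "free_vis")
  grid <- expand.grid(participant = sprintf("P%02d", 1:n), task = tasks,
                      stringsAsFactors = FALSE)
  grid$counterbalance <- rep(1:5, length.out = nrow(grid))
  pvals <- replicate(150, {
    u <- setNames(rnorm(n, 0, 0.5), sprintf("P%02d", 1:n))
    grid$composite <- u[grid$participant] + rnorm(nrow(grid), 0, 0.8)
    ratings_task_lrt(grid)$p
  })
  # p-values approximately uniform under the null
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.05)
})
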