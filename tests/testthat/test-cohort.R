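small_cfg <- function(n = 40, seed = 9, ...) {
  generator_config(n_participants = n, seed = seed, ...)
}

test_that("pass probability is the logistic-with-lapse psychometric function", {
  expect_equal(pass_probability(response_model(6, 1, 0), 6), 0.5)
  expect_equal(pass_probability(response_model(6, 1, 0.02), -100), 0.99)
  expect_equal(pass_probability(response_model(6, 0.8, 0), 8),
               plogis(-2.5), tolerance = 1e-12)
  # strictly decreasing in level, bounded by the lapse asymptotes
  m <- response_model(5, 0.6, 0.04)
  p <- pass_probability(m, 1:10)
  expect_true(all(diff(p) < 0))
  expect_true(all(p > 0.02 & p < 0.98))
  expect_error(response_model(5, 0), "slope")
  expect_error(response_model(5, 1, 0.6), "lapse")
})

test_that("cohort generation is seed-deterministic with the configured structure", {
  cfg <- small_cfg()
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  expect_equal(nrow(generate_cohort(small_cfg(n = 0))), 0L)
  prof <- generate_cohort(cfg)
  expect_true(all(prof$age >= 18 & prof$age <= 65))
  expect_equal(unname(table(prof$counterbalance)), rep(8L, 5),
               ignore_attr = TRUE)
})

test_that("session-2 capacity is correlated at the configured retest level", {
  cfg <- generator_config(n_participants = 5000, seed = 21, retest_rho = 0.8)
  prof <- generate_cohort(cfg)
  expect_equal(cor(prof$theta, prof$theta_session2), 0.8, tolerance = 0.03)
  # extraversion latent independent of capacity
  expect_lt(abs(cor(prof$theta, prof$extraversion_latent)), 0.05)
})

test_that("generated trial tables match the task design constants", {
  cfg <- small_cfg()
  ds <- generate_dataset(generate_cohort(cfg), cfg)
  t <- ds$tables
  per <- function(tab) unname(table(tab$participant))
  expect_true(all(per(t$sandwich_s1) == 13))  # practice + 12 test
  expect_true(all(per(t$digit_span_aud) == 36))
  expect_true(all(per(t$free_recall_vis) == 6))
  expect_true(all(per(t$transcription_noise) == 17))   # 16 + catch
  expect_true(all(per(t$transcription_accent) == 25))  # 24 + catch
  expect_true(all(per(t$ratings) == 15))  # 5 tasks x 3 measures
  expect_true(all(per(t$extraversion) == 9))  # 8 items + attention check
  # every participant id in every table comes from the profile list
  prof <- generate_cohort(cfg)
  for (tab in t)
    expect_true(all(tab$participant %in% prof$id))
  # digit-span levels 2..10 with 4 trials each
  one <- t$digit_span_aud[t$digit_span_aud$participant == prof$id[1], ]
  expect_equal(unname(table(one$list_length)), rep(4L, 9),
               ignore_attr = TRUE)
  # catch trials are always passed in full
  catch <- t$transcription_noise[t$transcription_noise$item == "catch", ]
  expect_true(all(catch$response == "i am paying attention"))
})

test_that("dataset export is byte-identical across runs with the same seed", {
  cfg <- small_cfg(n = 15)
  d1 <- tempfile(); d2 <- tempfile()
  write_cohort_csv(generate_dataset(generate_cohort(cfg), cfg), d1)
  write_cohort_csv(generate_dataset(generate_cohort(cfg), cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("effect-nulled transcription shows no span-accuracy correlation", {
  set.seed(31)
  span <- rnorm(2000, 5, 1.4)
  age <- runif(2000, 18, 65)
  counts <- simulate_transcription_counts(
    span, age, n_items = 8, coefs = c(0.5, 0, 0, 0))
  acc <- tapply(counts$n_correct, counts$subject, sum) /
    tapply(counts$n_correct + counts$n_missed, counts$subject, sum)
  spans <- tapply(counts$span_score, counts$subject, mean)
  expect_lt(abs(cor(acc, spans)), 0.05)
})

test_that("transcription generation carries the configured effects into the counts", {
  set.seed(32)
  span <- rnorm(300, 5, 1.4)
  age <- runif(300, 18, 65)
  counts <- simulate_transcription_counts(
    span, age, n_items = 16, coefs = c(0, 0.26, -0.07, 0.01))
  acc <- tapply(counts$n_correct, counts$subject, sum) / (16 * 4)
  spans <- tapply(counts$span_score, counts$subject, mean)
  expect_gt(cor(acc, spans), 0.15)
  # row bookkeeping: counts always sum to the keyword total
  expect_true(all(counts$n_correct + counts$n_missed == 4))
})
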