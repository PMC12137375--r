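test_that("base-plus-partial-credit rule reproduces the worked examples", {
  s <- sandwich_score(c(`4` = 2, `5` = 3, `6` = 2, `7` = 1))
  expect_equal(s$base, 6)
  expect_equal(s$partial, 0.5)
  expect_equal(s$final, 6.5)
  expect_equal(sandwich_score(c(`5` = 3, `6` = 2, `7` = 1, `8` = 1,
                                `9` = 1))$partial, 1.5)
  expect_equal(sandwich_score(c(`5` = 2, `6` = 2))$base, 6)
  # no level passed twice: zero base, every pass is partial credit
  empty <- sandwich_score(setNames(integer(0), character(0)))
  expect_equal(empty$final, 0)
  expect_equal(sandwich_score(c(`5` = 1, `7` = 1))$final, 1)
})

test_that("pass profiles aggregate test trials only", {
  up <- run_session(responder_always(TRUE))
  expect_identical(pass_profile(up),
                   setNames(c(1L, 1L, 1L, 1L, 1L, 7L), as.character(5:10)))
  down <- run_session(responder_always(FALSE))
  expect_length(pass_profile(down), 0L)
  alt <- run_session(responder_alternating(first = TRUE))
  expect_identical(pass_profile(alt), setNames(6L, "5"))
  expect_equal(score_session(alt)$final, 5 + 0)  # 6 passes at base level 5
})

test_that("sandwich_score agrees with the brute-force oracle on sampled staircase paths", {
  # a spread of the 4096 outcome paths; the acceptance suite runs them all
  paths <- enumerate_paths(staircase_rule())
  idx <- unique(c(1L, seq(1L, 4096L, by = 7L), 4096L))
  finals <- vapply(paths[idx], function(p) {
    prof <- pass_profile(data.frame(level = p$levels, passed = p$outcomes,
                                    is_practice = FALSE))
    got <- sandwich_score(prof)
    want <- oracle_span_score(p$levels, p$outcomes)
    if (got$base != want$base || got$partial != want$partial)
      stop("oracle mismatch")
    got$final
  }, numeric(1))
  expect_true(all(finals >= 0 & finals <= 10))
  expect_equal(finals[[length(finals)]], 10)  # all-pass path (last in the expansion)
  expect_equal(finals[[1]], 0)                # all-fail path
})

test_that("mean-span rule adds summed proportions to the baseline", {
  expect_equal(mean_span(c(1, rep(0, 8))), 2.00)
  expect_equal(mean_span(rep(1, 9)), 10.00)
  expect_equal(mean_span(c(1, 0.75, 0.25, rep(0, 6))), 3.00)
  expect_equal(mean_span(rep(0, 9)), 1.00)
  expect_error(mean_span(c(1.2, rep(0, 8))), "\\[0, 1\\]")
  # linear in each proportion
  base <- mean_span(c(0.5, rep(0, 8)))
  expect_equal(mean_span(c(0.75, rep(0, 8))) - base, 0.25)
})

test_that("serial trials pass only on a perfect ordered digit match", {
  expect_true(score_serial_trial("5 6 3", c(5, 6, 3)))
  expect_true(score_serial_trial("5, 6, 3.", "563"))
  expect_false(score_serial_trial("536", "563"))
  expect_false(score_serial_trial("56", "563"))
  expect_false(score_serial_trial("", "563"))
})

test_that("free recall is order-free, case-insensitive, credits each target once", {
  targets <- c("market", "college", "river", "garden", "window", "bottle",
               "doctor", "mountain", "pencil", "bridge")
  expect_equal(free_recall_trial_score(paste(rev(targets), collapse = " "),
                                       targets), 10L)
  expect_equal(free_recall_trial_score("market market market", targets), 1L)
  expect_equal(free_recall_trial_score("Market COLLEGE river zebra apple cat dog",
                                       targets), 3L)
  expect_equal(free_recall_trial_score("", targets), 0L)
})

test_that("keyword scoring applies the lenient-matching rules", {
  rules <- keyword_ruleset()
  s <- keyword_score("grey mouse ate cheese",
                     c("gray", "mouse", "ate", "cheese"), rules)
  expect_equal(s$n_correct, 4L)
  expect_equal(s$n_missed, 0L)
  expect_equal(keyword_score("she swipe the card",
                             c("swiped", "card", "blue", "pen"),
                             rules)$n_correct, 2L)
  expect_equal(keyword_score("a leter and one stamp",
                             c("letter", "one", "stamp", "red"),
                             rules)$n_correct, 3L)
  expect_equal(keyword_score("I got 1 apple",
                             c("one", "apples", "pear", "plum"),
                             rules)$n_correct, 2L)
  empty <- keyword_score("", c("a1", "b2", "c3", "d4"), rules)
  expect_equal(empty$n_correct, 0L)
  expect_equal(empty$n_missed, 4L)
})

test_that("keyword scoring is one-to-one and order-insensitive", {
  rules <- keyword_ruleset()
  # one token cannot satisfy two keywords
  expect_equal(keyword_score("mouse", c("mouse", "mouse", "cat", "dog"),
                             rules)$n_correct, 1L)
  # response token order does not change the count
  kw <- c("gray", "mouse", "ate", "cheese")
  resp <- c("cheese", "grey", "ate", "mouse")
  perms <- list(1:4, 4:1, c(2, 4, 1, 3), c(3, 1, 4, 2))
  counts <- vapply(perms, function(p)
    keyword_score(paste(resp[p], collapse = " "), kw, rules)$n_correct,
    integer(1))
  expect_true(all(counts == 4L))
  # never exceeds the keyword count
  expect_lte(keyword_score(paste(rep("mouse", 10), collapse = " "),
                           c("mouse", "cat", "dog", "elk"),
                           rules)$n_correct, 4L)
})

test_that("rules can be disabled independently and short stems are protected", {
  strict <- keyword_ruleset(tense = FALSE, plural = FALSE,
                            double_letter = FALSE, number_text = FALSE,
                            lexicon = NULL)
  expect_equal(keyword_score("grey swipe leter 1",
                             c("gray", "swiped", "letter", "one"),
                             strict)$n_correct, 0L)
  # suffix rules require a stem of at least 3 characters
  rules <- keyword_ruleset()
  expect_equal(keyword_score("as", c("a", "x1", "x2", "x3"),
                             rules)$n_correct, 0L)
})

test_that("lexicon round-trips through a plain-text file", {
  path <- tempfile(fileext = ".txt")
  writeLines(c("gray grey", "absent abcent"), path)
  lx <- read_lexicon(path)
  expect_equal(dim(lx), c(2L, 2L))
  s <- keyword_score("abcent", c("absent", "x1", "x2", "x3"),
                     keyword_ruleset(lexicon = lx))
  expect_equal(s$n_correct, 1L)
})

test_that("extraversion composite reverse-keys three of eight items", {
  expect_equal(extraversion_composite(rep(3, 8)), 3.0)
  expect_equal(extraversion_composite(rep(5, 8)), (5 * 5 + 3 * 1) / 8)
  expect_equal(extraversion_composite(c(2, rep(3, 7)), reverse_items = 1L),
               mean(c(4, rep(3, 7))))
  # flipping a response together with its keying leaves the composite fixed
  resp <- c(4, 2, 5, 1, 3, 4, 2, 5)
  a <- extraversion_composite(resp, c(2, 5, 7))
  resp2 <- resp; resp2[3] <- 6 - resp2[3]
  b <- extraversion_composite(resp2, c(2, 3, 5, 7))
  expect_equal(a, b)
  expect_error(extraversion_composite(c(0, rep(3, 7))), "1..5")
})
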