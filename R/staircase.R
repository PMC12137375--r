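#' Staircase rule for the adaptive span game
#'
#' Defines the one-up/one-down adaptive trial flow: one practice trial at
#' `practice_level`, then `n_test_trials` test trials starting at
#' `start_level`, moving up `step` levels after a pass and down `step` levels
#' after a fail, clamped to `[floor, ceiling]`. Defaults reproduce the span
#' game's design: a Level 1 practice trial followed by 12 test trials
#' starting at Level 5 on a 1--10 level range.
#'
#' @param start_level First test-trial level.
#' @param step Level increment/decrement per trial.
#' @param floor,ceiling Lowest and highest admissible levels. A pass at the
#'   ceiling or a fail at the floor leaves the level unchanged.
#' @param n_test_trials Number of scored test trials.
#' @param practice_level Level of the single unscored practice trial.
#' @return An object of class `staircase_rule`.
#' @examples
#' staircase_rule()
#' @export
staircase_rule <- function(start_level = 5L, step = 1L, floor = 1L,
                           ceiling = 10L, n_test_trials = 12L,
                           practice_level = 1L) {
  start_level <- as.integer(start_level)
  step <- as.integer(step)
  floor <- as.integer(floor)
  ceiling <- as.integer(ceiling)
  n_test_trials <- as.integer(n_test_trials)
  practice_level <- as.integer(practice_level)
  if (step < 1L) stop("`step` must be a positive integer")
  if (floor > ceiling) stop("`floor` must not exceed `ceiling`")
  if (start_level < floor || start_level > ceiling)
    stop("`start_level` must lie in [floor, ceiling]")
  if (n_test_trials < 0L) stop("`n_test_trials` must be >= 0")
  structure(
    list(start_level = start_level, step = step, floor = floor,
         ceiling = ceiling, n_test_trials = n_test_trials,
         practice_level = practice_level),
    class = "staircase_rule"
  )
}

#' @export
print.staircase_rule <- function(x, ...) {
  cat(sprintf(
    "Staircase rule: start %d, +/-%d per trial, levels [%d, %d], %d test trials (practice at %d)\n",
    x$start_level, x$step, x$floor, x$ceiling, x$n_test_trials,
    x$practice_level))
  invisible(x)
}

#' Next level under the staircase rule
#'
#' A pass moves the participant up one step in difficulty, a fail moves them
#' down one step; the result is clamped to the rule's level range.
#'
#' @param current Current level (must lie within the rule's range).
#' @param passed Logical; did the participant pass the current trial?
#' @param rule A [staircase_rule()].
#' @return The next trial's level (integer).
#' @examples
#' next_level(5, TRUE)   # 6
#' next_level(5, FALSE)  # 4
#' next_level(10, TRUE)  # clamped at the ceiling: 10
#' @export
next_level <- function(current, passed, rule = staircase_rule()) {
  stopifnot(inherits(rule, "staircase_rule"))
  current <- as.integer(current)
  if (any(current < rule$floor | current > rule$ceiling))
    stop("`current` outside [floor, ceiling]")
  nxt <- ifelse(passed, current + rule$step, current - rule$step)
  pmin(pmax(nxt, rule$floor), rule$ceiling)
}

#' Simulate one session of the adaptive span game
#'
#' Runs the practice trial followed by the chained test trials. The responder
#' is a function `level -> TRUE/FALSE`; it may be stochastic, in which case
#' the session is reproducible given `seed`.
#'
#' @param responder Function of a single level returning a pass flag.
#' @param rule A [staircase_rule()].
#' @param seed Optional integer seed applied before the first trial.
#' @param participant,session Identifiers stored in the record.
#' @return A `session_record`: a data.frame with columns `participant`,
#'   `session`, `trial_index`, `level`, `passed`, `is_practice`. The practice
#'   trial has `trial_index = 0` and is excluded from all scoring.
#' @examples
#' rec <- run_session(function(level) TRUE)
#' rec$level[!rec$is_practice]
#' @export
run_session <- function(responder, rule = staircase_rule(), seed = NULL,
                        participant = "P1", session = 1L) {
  stopifnot(inherits(rule, "staircase_rule"), is.function(responder))
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- rule$n_test_trials
  levels <- integer(n)
  passed <- logical(n)
  practice_pass <- isTRUE(responder(rule$practice_level))
  lvl <- rule$start_level
  for (i in seq_len(n)) {
    levels[i] <- lvl
    passed[i] <- isTRUE(responder(lvl))
    lvl <- next_level(lvl, passed[i], rule)
  }
  rec <- data.frame(
    participant = participant,
    session = as.integer(session),
    trial_index = c(0L, seq_len(n)),
    level = c(rule$practice_level, levels),
    passed = c(practice_pass, passed),
    is_practice = c(TRUE, rep(FALSE, n)),
    stringsAsFactors = FALSE
  )
  class(rec) <- c("session_record", "data.frame")
  rec
}

#' Enumerate all staircase outcome paths
#'
#' Exhaustively lists every pass/fail sequence over the test trials together
#' with the level sequence the rule induces. Used as the test oracle for
#' scoring: with 12 test trials there are 2^12 = 4096 paths.
#'
#' @param rule A [staircase_rule()]; `n_test_trials` must be at most 20.
#' @return A list with one element per path, each a list with `outcomes`
#'   (logical vector) and `levels` (integer vector).
#' @examples
#' length(enumerate_paths(staircase_rule(n_test_trials = 2)))  # 4
#' @export
enumerate_paths <- function(rule = staircase_rule()) {
  stopifnot(inherits(rule, "staircase_rule"))
  n <- rule$n_test_trials
  if (n > 20L) stop("`n_test_trials` too large to enumerate (max 20)")
  if (n == 0L)
    return(list(list(outcomes = logical(0), levels = integer(0))))
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  lapply(seq_len(nrow(grid)), function(i) {
    outcomes <- as.logical(grid[i, ])
    levels <- integer(n)
    lvl <- rule$start_level
    for (j in seq_len(n)) {
      levels[j] <- lvl
      lvl <- next_level(lvl, outcomes[j], rule)
    }
    list(outcomes = outcomes, levels = levels)
  })
}
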