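#' Pass-count profile of a staircase session
#'
#' Tallies, per level, how many *test* trials were passed. The practice trial
#' and all failed trials are excluded.
#'
#' @param session A `session_record` from [run_session()] (or any data.frame
#'   with `level`, `passed`, `is_practice` columns).
#' @return Named integer vector: names are levels (as characters), values are
#'   pass counts. Levels with no passes are omitted.
#' @export
pass_profile <- function(session) {
  stopifnot(all(c("level", "passed", "is_practice") %in% names(session)))
  keep <- !session$is_practice & session$passed
  if (!any(keep)) return(stats::setNames(integer(0), character(0)))
  tab <- table(session$level[keep])
  stats::setNames(as.integer(tab), names(tab))
}

#' Base-plus-partial-credit span score
#'
#' The final span score sums a base score and a partial-credit score. The
#' base score is the highest level passed at least twice across the test
#' trials; each passed trial at a level strictly above the base earns 0.5
#' partial-credit points. A participant who never passes any level twice has
#' base 0, and every pass then counts toward partial credit.
#'
#' @param profile Pass-count profile as returned by [pass_profile()]: a named
#'   numeric vector mapping level to number of passed trials.
#' @return A list of class `span_score` with components `base`, `partial`,
#'   and `final` (= base + partial).
#' @examples
#' # passed Level 4 twice, Level 5 three times, Level 6 twice, Level 7 once:
#' sandwich_score(c(`4` = 2, `5` = 3, `6` = 2, `7` = 1))  # final 6.5
#' @export
sandwich_score <- function(profile) {
  profile <- profile[profile > 0]
  if (length(profile) && (is.null(names(profile)) ||
                          anyNA(suppressWarnings(as.numeric(names(profile))))))
    stop("`profile` must be named by level")
  levels <- as.numeric(names(profile))
  counts <- as.numeric(profile)
  if (any(counts < 0)) stop("pass counts must be >= 0")
  twice <- levels[counts >= 2]
  base <- if (length(twice)) max(twice) else 0
  partial <- 0.5 * sum(counts[levels > base])
  structure(list(base = base, partial = partial, final = base + partial),
            class = "span_score")
}

#' @export
print.span_score <- function(x, ...) {
  cat(sprintf("Span score: base %.1f + partial %.1f = %.1f\n",
              x$base, x$partial, x$final))
  invisible(x)
}

#' Score a full staircase session
#'
#' Convenience wrapper: [pass_profile()] followed by [sandwich_score()].
#'
#' @inheritParams pass_profile
#' @return A `span_score`.
#' @export
score_session <- function(session) sandwich_score(pass_profile(session))

#' Mean-span score for a fixed-ladder span task
#'
#' Under the mean-span rule the proportion of correct trials is computed per
#' list length, and the span estimate is a baseline of 1.00 (one less than
#' the first tested length, 2) plus the sum of those proportions. With four
#' trials per length the proportions take values 0, 0.25, 0.5, 0.75, 1 and
#' scores range from 1.00 (nothing correct) to 10.00 (everything correct).
#'
#' @param proportions Numeric vector of per-length proportions correct, one
#'   entry per tested list length (lengths 2--10 by default). Values must lie
#'   in `[0, 1]`.
#' @param baseline Baseline added to the summed proportions (default 1).
#' @return The mean-span score.
#' @examples
#' mean_span(c(1, 0, 0, 0, 0, 0, 0, 0, 0))  # perfect at length 2 only: 2.00
#' mean_span(rep(1, 9))                      # ceiling: 10.00
#' @export
mean_span <- function(proportions, baseline = 1) {
  proportions <- as.numeric(proportions)
  if (any(is.na(proportions)) || any(proportions < 0 | proportions > 1))
    stop("`proportions` must lie in [0, 1]")
  baseline + sum(proportions)
}

#' Score one serial-recall (digit span) trial
#'
#' The typed response is compared to the target digit string after removing
#' spaces and punctuation; the trial passes only on a perfect ordered match.
#'
#' @param response Typed response text.
#' @param target Target digit sequence: a string, or a numeric vector that is
#'   concatenated.
#' @return Logical pass flag.
#' @examples
#' score_serial_trial("5 6 3", c(5, 6, 3))  # TRUE
#' score_serial_trial("536", "563")         # FALSE
#' @export
score_serial_trial <- function(response, target) {
  norm <- function(x) gsub("[^0-9]", "", paste(x, collapse = ""))
  resp <- norm(response)
  targ <- norm(target)
  nzchar(targ) && identical(resp, targ)
}

#' Score one free-recall trial
#'
#' Order-free scoring: the number of distinct target words present among the
#' response tokens, case-insensitively, each target credited at most once.
#' Intrusions (non-target words) and repetitions are ignored.
#'
#' @param response Response: a character vector of words, or a single string
#'   that is split on whitespace.
#' @param targets Character vector of distinct target words (10 per trial in
#'   the task design).
#' @return Integer count of recalled targets, 0 to `length(targets)`.
#' @examples
#' free_recall_trial_score("college market", c("market", "college", "ranch"))
#' @export
free_recall_trial_score <- function(response, targets) {
  targets <- tolower(targets)
  if (anyDuplicated(targets)) stop("`targets` must be distinct")
  tokens <- tolower(unlist(strsplit(paste(response, collapse = " "), "\\s+")))
  tokens <- gsub("[^a-z0-9']", "", tokens)
  sum(targets %in% tokens)
}

# -- keyword (transcription) scoring -----------------------------------------

number_word_map <- local({
  words <- c("zero", "one", "two", "three", "four", "five", "six", "seven",
             "eight", "nine", "ten", "eleven", "twelve", "thirteen",
             "fourteen", "fifteen", "sixteen", "seventeen", "eighteen",
             "nineteen", "twenty", "thirty", "forty", "fifty", "sixty",
             "seventy", "eighty", "ninety", "hundred")
  vals <- c(0:20, seq(30, 90, 10), 100)
  stats::setNames(as.character(vals), words)
})

#' Rule set for keyword transcription scoring
#'
#' Lenient-matching rules for scoring typed sentence transcriptions against
#' keywords: the tense rule treats suffix variation such as "swipe" vs.
#' "swiped" as correct; the plural rule treats "apple" vs. "apples" as
#' correct; the double-letter rule treats "leter" vs. "letter" as correct;
#' the number-text rule treats "1" vs. "one" as correct; and a misspelling
#' lexicon accepts listed equivalent pairs such as "gray" vs. "grey".
#'
#' @param tense,plural,double_letter,number_text Logical flags enabling each
#'   rule.
#' @param lexicon Two-column character matrix or data.frame of equivalent
#'   word pairs (treated symmetrically), or `NULL`.
#' @return An object of class `keyword_ruleset`.
#' @seealso [keyword_score()], [read_lexicon()]
#' @export
keyword_ruleset <- function(tense = TRUE, plural = TRUE, double_letter = TRUE,
                            number_text = TRUE, lexicon = default_lexicon()) {
  if (!is.null(lexicon)) {
    lexicon <- as.matrix(lexicon)
    if (ncol(lexicon) != 2) stop("`lexicon` must have two columns")
    lexicon <- apply(lexicon, 2, tolower)
    if (is.null(dim(lexicon))) lexicon <- matrix(lexicon, ncol = 2)
  }
  structure(list(tense = isTRUE(tense), plural = isTRUE(plural),
                 double_letter = isTRUE(double_letter),
                 number_text = isTRUE(number_text), lexicon = lexicon),
            class = "keyword_ruleset")
}

#' Built-in misspelling lexicon
#'
#' A small set of common acceptable misspellings / spelling variants used by
#' default in [keyword_ruleset()].
#'
#' @return Two-column character matrix of equivalent pairs.
#' @export
default_lexicon <- function() {
  matrix(c(
    "gray", "grey",
    "absent", "abcent",
    "color", "colour",
    "theater", "theatre",
    "donut", "doughnut",
    "whisky", "whiskey"
  ), ncol = 2, byrow = TRUE)
}

#' Read a misspelling lexicon from a two-column text file
#'
#' @param path Path to a whitespace- or comma-separated two-column file.
#' @return Two-column character matrix suitable for [keyword_ruleset()].
#' @export
read_lexicon <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "",
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) == 1)
    df <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) != 2) stop("lexicon file must have two columns")
  as.matrix(df)
}

# strip punctuation, lowercase, split on whitespace
tokenize_response <- function(text) {
  tokens <- unlist(strsplit(tolower(paste(text, collapse = " ")), "\\s+"))
  tokens <- gsub("[^a-z0-9']", "", tokens)
  tokens[nzchar(tokens)]
}

# suffix stripping helper: equality after removing any listed suffix from
# either side, provided the remaining stem has >= 3 characters
match_suffix <- function(a, b, suffixes) {
  variants <- function(w) {
    out <- w
    for (s in suffixes) {
      if (endsWith(w, s) && nchar(w) - nchar(s) >= 3)
        out <- c(out, substr(w, 1, nchar(w) - nchar(s)))
    }
    out
  }
  length(intersect(variants(a), variants(b))) > 0
}

# collapse runs of a repeated letter: "letter" -> "leter"
squeeze_doubles <- function(w) gsub("(.)\\1+", "\\1", w)

canonical_number <- function(w) {
  if (grepl("^[0-9]+$", w)) return(w)
  if (w %in% names(number_word_map)) return(unname(number_word_map[[w]]))
  NA_character_
}

token_matches_keyword <- function(token, keyword, rules) {
  if (identical(token, keyword)) return(TRUE)
  if (rules$tense && match_suffix(token, keyword, c("ed", "d", "ing")))
    return(TRUE)
  if (rules$plural && match_suffix(token, keyword, c("es", "s")))
    return(TRUE)
  if (rules$double_letter &&
      identical(squeeze_doubles(token), squeeze_doubles(keyword)))
    return(TRUE)
  if (rules$number_text) {
    ct <- canonical_number(token); ck <- canonical_number(keyword)
    if (!is.na(ct) && !is.na(ck) && identical(ct, ck)) return(TRUE)
  }
  if (!is.null(rules$lexicon)) {
    lx <- rules$lexicon
    hit <- (lx[, 1] == token & lx[, 2] == keyword) |
      (lx[, 2] == token & lx[, 1] == keyword)
    if (any(hit)) return(TRUE)
  }
  FALSE
}

#' Score a sentence transcription against its keywords
#'
#' Tokenizes the typed response (lowercased, punctuation stripped) and counts
#' how many keywords are correctly identified versus missed. Matching is
#' one-to-one: each keyword consumes at most one response token and each
#' token can satisfy at most one keyword; assignment is greedy in keyword
#' order, taking the first unmatched matching token. Lenient-matching rules
#' (tense, plural, double letter, number-text, misspelling lexicon) are
#' applied as configured.
#'
#' @param response Typed response text.
#' @param keywords Character vector of keywords (4 per sentence in the task
#'   design).
#' @param rules A [keyword_ruleset()].
#' @param n_keywords Expected keyword count; set `NULL` to skip the check.
#' @return A list of class `keyword_score` with `n_correct` and `n_missed`
#'   (summing to `length(keywords)`).
#' @examples
#' keyword_score("the grey mouse ate the cheese",
#'               c("gray", "mouse", "ate", "cheese"))
#' @export
keyword_score <- function(response, keywords, rules = keyword_ruleset(),
                          n_keywords = 4L) {
  stopifnot(inherits(rules, "keyword_ruleset"))
  keywords <- tolower(as.character(keywords))
  if (!is.null(n_keywords) && length(keywords) != n_keywords)
    stop(sprintf("expected %d keywords, got %d", n_keywords,
                 length(keywords)))
  tokens <- tokenize_response(response)
  used <- logical(length(tokens))
  n_correct <- 0L
  for (kw in keywords) {
    for (j in seq_along(tokens)) {
      if (!used[j] && token_matches_keyword(tokens[j], kw, rules)) {
        used[j] <- TRUE
        n_correct <- n_correct + 1L
        break
      }
    }
  }
  structure(list(n_correct = n_correct,
                 n_missed = length(keywords) - n_correct),
            class = "keyword_score")
}

#' Extraversion composite from Likert items
#'
#' Eight items on a 1--5 agreement scale, three of which are reverse-scored
#' (a reverse-keyed response x contributes 6 - x); the composite is the mean
#' of the keyed values.
#'
#' @param responses Numeric vector of item responses in 1--5.
#' @param reverse_items Integer indices of the reverse-scored items
#'   (default items 2, 5, 7 of the eight-item set).
#' @return Composite score in `[1, 5]`.
#' @examples
#' extraversion_composite(rep(3, 8))  # midpoint is invariant: 3
#' @export
extraversion_composite <- function(responses, reverse_items = c(2L, 5L, 7L)) {
  responses <- as.numeric(responses)
  if (any(is.na(responses)) || any(responses < 1 | responses > 5))
    stop("`responses` must lie in 1..5")
  if (length(reverse_items) &&
      (min(reverse_items) < 1 || max(reverse_items) > length(responses)))
    stop("`reverse_items` out of range")
  keyed <- responses
  keyed[reverse_items] <- 6 - keyed[reverse_items]
  mean(keyed)
}
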