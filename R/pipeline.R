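#' Column schemas of the trial-level CSV tables
#'
#' Named list mapping schema names to required columns with expected types.
#' Schemas: `sandwich` (staircase sessions), `serial_span` (digit span),
#' `free_recall`, `transcription`, `ratings`, `scores`, `extraversion`.
#'
#' @return Named list of named character vectors (column -> type).
#' @export
trial_schemas <- function() {
  list(
    sandwich = c(participant = "character", session = "integer",
                 trial_index = "integer", level = "integer",
                 passed = "logical", is_practice = "logical"),
    serial_span = c(participant = "character", task = "character",
                    trial_index = "integer", list_length = "integer",
                    target = "character", response = "character"),
    free_recall = c(participant = "character", task = "character",
                    trial_index = "integer", targets = "character",
                    response = "character"),
    transcription = c(participant = "character", task = "character",
                      item = "character", keywords = "character",
                      response = "character", age = "numeric"),
    ratings = c(participant = "character", task = "character",
                counterbalance = "integer", measure = "character",
                value = "numeric"),
    scores = c(participant = "character", task = "character",
               session = "integer", score = "numeric"),
    extraversion = c(participant = "character", item = "character",
                     reverse = "logical", value = "integer")
  )
}

coerce_column <- function(x, type, col) {
  out <- switch(type,
    character = as.character(x),
    integer = suppressWarnings(as.integer(x)),
    numeric = suppressWarnings(as.numeric(x)),
    logical = if (is.character(x))
      as.logical(toupper(x)) else as.logical(x),
    stop("unknown type ", type))
  if (!is.character(out) && anyNA(out) & !anyNA(x)) {
    bad <- which(is.na(out) & !is.na(x))[1]
    stop(sprintf("column `%s`: cannot coerce row %d to %s", col, bad, type))
  }
  out
}

#' Read and validate a trial-level CSV against a named schema
#'
#' @param path Path to a CSV file with a header row.
#' @param schema Schema name; one of `names(trial_schemas())`.
#' @return Validated data.frame with columns coerced to the schema types.
#' @export
load_trial_table <- function(path, schema) {
  schemas <- trial_schemas()
  if (!schema %in% names(schemas))
    stop("unknown schema `", schema, "`; available: ",
         paste(names(schemas), collapse = ", "))
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  spec <- schemas[[schema]]
  missing <- setdiff(names(spec), names(df))
  if (length(missing))
    stop("schema `", schema, "`: missing column(s) ",
         paste0("`", missing, "`", collapse = ", "))
  for (col in names(spec)) df[[col]] <- coerce_column(df[[col]], spec[[col]],
                                                      col)
  df
}

# -- scoring drivers ---------------------------------------------------------

#' Score every task of a cohort dataset
#'
#' Applies the task-specific scoring rules to the trial tables: the
#' base-plus-partial-credit rule to both staircase sessions, the mean-span
#' rule to the digit-span ladders, order-free matching to free recall, the
#' rule-based keyword scorer to the transcription tables (catch trials
#' excluded), and the reverse-keyed mean to the extraversion items
#' (attention check excluded).
#'
#' @param dataset A `cohort_dataset`, or a bare list of its trial tables.
#' @param rules A [keyword_ruleset()] for transcription scoring.
#' @return List of class `cohort_scores`:
#'   `scores` — long per-participant table (participant, task, session,
#'   score) covering the five span tasks;
#'   `transcription` — list with `noise` and `accent` grouped-binomial
#'   tables (subject, item, n_correct, n_missed, span_score, age);
#'   `extraversion` — per-participant composite table.
#' @export
score_cohort <- function(dataset, rules = keyword_ruleset()) {
  tables <- if (inherits(dataset, "cohort_dataset")) dataset$tables
    else dataset
  # staircase sessions
  sb_scores <- function(tab, session) {
    by_p <- split(tab, tab$participant)
    data.frame(participant = names(by_p), task = "sandwich",
               session = session,
               score = vapply(by_p, function(s) score_session(s)$final,
                              numeric(1)),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  # fixed-ladder span via the mean-span rule
  ds_scores <- function(tab) {
    by_p <- split(tab, tab$participant)
    data.frame(participant = names(by_p), task = tab$task[1], session = 1L,
               score = vapply(by_p, function(s) {
                 pass <- mapply(score_serial_trial, s$response, s$target)
                 props <- tapply(pass, s$list_length, mean)
                 mean_span(props)
               }, numeric(1)),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  fr_scores <- function(tab) {
    by_p <- split(tab, tab$participant)
    data.frame(participant = names(by_p), task = tab$task[1], session = 1L,
               score = vapply(by_p, function(s) {
                 counts <- mapply(function(r, tg)
                   free_recall_trial_score(r, strsplit(tg, ";")[[1]]),
                   s$response, s$targets)
                 mean(counts)
               }, numeric(1)),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  scores <- rbind(
    sb_scores(tables$sandwich_s1, 1L), sb_scores(tables$sandwich_s2, 2L),
    ds_scores(tables$digit_span_aud), ds_scores(tables$digit_span_vis),
    fr_scores(tables$free_recall_aud), fr_scores(tables$free_recall_vis))

  # transcription: keyword scoring, catch trials excluded; span covariate is
  # the session-2 staircase score
  s2 <- scores[scores$task == "sandwich" & scores$session == 2L, ]
  span_of <- stats::setNames(s2$score, s2$participant)
  trans_scored <- function(tab) {
    tab <- tab[tab$item != "catch", , drop = FALSE]
    kw <- strsplit(tab$keywords, ";")
    sc <- mapply(function(resp, k)
      keyword_score(resp, k, rules, n_keywords = NULL)$n_correct,
      tab$response, kw)
    data.frame(subject = tab$participant, item = tab$item,
               n_correct = as.integer(sc),
               n_missed = lengths(kw) - as.integer(sc),
               span_score = as.numeric(span_of[tab$participant]),
               age = tab$age, stringsAsFactors = FALSE, row.names = NULL)
  }
  # extraversion composite per participant (attention check excluded)
  ext <- tables$extraversion
  ext <- ext[ext$item != "attention_check", , drop = FALSE]
  by_p <- split(ext, ext$participant)
  extraversion <- data.frame(
    participant = names(by_p),
    composite = vapply(by_p, function(s) {
      ord <- order(s$item)
      extraversion_composite(s$value[ord], which(s$reverse[ord]))
    }, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)

  structure(list(
    scores = scores,
    transcription = list(noise = trans_scored(tables$transcription_noise),
                         accent = trans_scored(tables$transcription_accent)),
    extraversion = extraversion
  ), class = "cohort_scores")
}

#' Reshape the long score table to one row per participant
#'
#' @param scores Long score table from [score_cohort()].
#' @param session Session to keep for the span game (default 1).
#' @return Wide data.frame: `participant` plus one column per task.
#' @export
scores_wide <- function(scores, session = 1L) {
  keep <- scores$session == session |
    (scores$task != "sandwich" & scores$session == 1L)
  s <- scores[keep, ]
  out <- stats::reshape(s[, c("participant", "task", "score")],
                        idvar = "participant", timevar = "task",
                        direction = "wide")
  names(out) <- sub("^score\\.", "", names(out))
  rownames(out) <- NULL
  out
}

# -- end-to-end pipeline -----------------------------------------------------

#' Run the full validation pipeline on a synthetic cohort
#'
#' Orchestrates simulate -> score -> validate -> power: generates the cohort
#' and trial data, scores every task, flags and removes retest outliers,
#' computes the convergent-validity correlation table (Bonferroni), the
#' two-way random-effects ICC, the discriminant-validity Bayes factor
#' against extraversion, the predictive-validity grouped-binomial mixed
#' models with likelihood-ratio tests (speech-in-noise with the span-by-age
#' interaction, accent without), and, optionally, the resampling power
#' curves. All randomness derives from `config$seed`.
#'
#' @param config A [generator_config()].
#' @param run_power Run the resampling power stage (default `TRUE`).
#' @param power_grid,power_iterations Grid and iterations for
#'   [resample_power()].
#' @param alpha Significance level used throughout.
#' @param family_size Bonferroni family size (default 10).
#' @param icc_type ICC form (`"agreement"` or `"consistency"`).
#' @param bf_kappa Stretched-beta prior width for the Bayes factor.
#' @param outlier_threshold Retest outlier threshold in mean absolute
#'   deviations (default 5).
#' @param outdir Optional directory; when given, the trial CSVs, score table
#'   and a text report are written there.
#' @return List of class `report_bundle`: `scores`, `correlations`, `icc`,
#'   `discriminant` (r and `bf_result`), `predictive` (per task: fit and
#'   LRTs), `power` (per task curve, or `"skipped"`), `outliers`,
#'   `manifest`.
#' @export
run_validation_pipeline <- function(config = generator_config(),
                                    run_power = TRUE,
                                    power_grid = seq(10L, 150L, 10L),
                                    power_iterations = 1000L,
                                    alpha = 0.05, family_size = 10L,
                                    icc_type = "agreement", bf_kappa = 1,
                                    outlier_threshold = 5,
                                    outdir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE))
  }
  profiles <- stage("simulate", generate_cohort(config))
  dataset <- stage("simulate", generate_dataset(profiles, config))
  scored <- stage("score", score_cohort(dataset))

  validate <- stage("validate", {
    sb1 <- scored$scores[scored$scores$task == "sandwich" &
                           scored$scores$session == 1L, ]
    sb2 <- scored$scores[scored$scores$task == "sandwich" &
                           scored$scores$session == 2L, ]
    sb2 <- sb2[match(sb1$participant, sb2$participant), ]
    flags <- flag_retest_outliers(sb1$score, sb2$score, outlier_threshold)
    dropped <- sb1$participant[flags]
    keep <- !(scored$scores$participant %in% dropped)
    scores_kept <- scored$scores[keep, ]
    wide <- scores_wide(scores_kept)
    task_cols <- c("sandwich", "digit_aud", "digit_vis", "free_aud",
                   "free_vis")
    correlations <- correlation_matrix(wide[, task_cols], family_size)
    s1k <- sb1[!flags, ]; s2k <- sb2[!flags, ]
    icc <- icc_two_way_random(s1k$score, s2k$score, type = icc_type)
    ext <- scored$extraversion
    ext <- ext[!(ext$participant %in% dropped), ]
    m <- match(ext$participant, s2k$participant)
    r_disc <- stats::cor(ext$composite, s2k$score[m])
    disc_bf <- bayes_cor_bf10(r_disc, nrow(ext), kappa = bf_kappa)
    predictive <- lapply(scored$transcription, function(tab) {
      tab <- tab[!(tab$subject %in% dropped), ]
      full <- fit_grouped_binomial_glmm(tab)
      no_int <- fit_grouped_binomial_glmm(tab, fixed = c("span", "age"))
      span_only <- fit_grouped_binomial_glmm(tab, fixed = "span")
      no_span <- fit_grouped_binomial_glmm(tab, fixed = "age")
      list(fit = full,
           lrt_span = likelihood_ratio_test(no_int, no_span),
           lrt_interaction = likelihood_ratio_test(full, no_int),
           lrt_age = likelihood_ratio_test(no_int, span_only))
    })
    list(outliers = dropped, scores = scores_kept,
         correlations = correlations, icc = icc,
         discriminant = list(r = r_disc, bf = disc_bf),
         predictive = predictive)
  })

  power <- if (run_power) stage("power", {
    lapply(scored$transcription, function(tab) {
      tab <- tab[!(tab$subject %in% validate$outliers), ]
      resample_power(tab, n_grid = power_grid,
                     iterations = power_iterations, alpha = alpha,
                     seed = config$seed + 2L)
    })
  }) else "skipped"

  bundle <- structure(list(
    scores = validate$scores,
    correlations = validate$correlations,
    icc = validate$icc,
    discriminant = validate$discriminant,
    predictive = validate$predictive,
    power = power,
    outliers = validate$outliers,
    manifest = dataset$manifest
  ), class = "report_bundle")

  if (!is.null(outdir)) {
    stage("report", {
      write_cohort_csv(dataset, file.path(outdir, "data"))
      utils::write.csv(validate$scores,
                       file.path(outdir, "scores.csv"), row.names = FALSE)
      utils::write.csv(as.data.frame(validate$correlations),
                       file.path(outdir, "correlations.csv"),
                       row.names = FALSE)
      if (!identical(power, "skipped"))
        for (nm in names(power))
          utils::write.csv(as.data.frame(power[[nm]]),
                           file.path(outdir, paste0("power_", nm, ".csv")),
                           row.names = FALSE)
      writeLines(utils::capture.output(print(bundle)),
                 file.path(outdir, "report.txt"))
    })
  }
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("== Validation report ==\n\n")
  cat("Retest outliers removed:", length(x$outliers), "\n\n")
  cat("-- Convergent validity (Pearson r, Bonferroni-adjusted p) --\n")
  print(as.data.frame(x$correlations), digits = 3)
  cat("\n-- Reliability --\n")
  print(x$icc)
  cat("\n-- Discriminant validity --\n")
  cat(sprintf("r(span game, extraversion) = %.3f\n", x$discriminant$r))
  print(x$discriminant$bf)
  cat("\n-- Predictive validity --\n")
  for (nm in names(x$predictive)) {
    p <- x$predictive[[nm]]
    cat(sprintf("[%s] span LRT: chi2 = %.2f, df = %d, p = %.3g; interaction LRT: chi2 = %.2f, p = %.3g\n",
                nm, p$lrt_span$chi2, p$lrt_span$df, p$lrt_span$p,
                p$lrt_interaction$chi2, p$lrt_interaction$p))
  }
  if (identical(x$power, "skipped")) {
    cat("\n-- Predictive power: skipped --\n")
  } else {
    cat("\n-- Predictive power --\n")
    for (nm in names(x$power)) {
      cr <- find_crossing(x$power[[nm]])
      cat(sprintf("[%s] 0.80 crossing: %s\n", nm,
                  if (!cr$reached) "not reached"
                  else sprintf("between n = %s and n = %s",
                               ifelse(is.na(cr$n_low), "<grid", cr$n_low),
                               cr$n_high)))
    }
  }
  invisible(x)
}
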