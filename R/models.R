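#' Center and scale a ratings composite
#'
#' Standardizes to mean 0 and unit sample standard deviation (n - 1
#' convention), as applied to the affect, fatigue and motivation composites
#' before modeling.
#'
#' @param values Numeric vector, length >= 2, non-constant.
#' @return Z-scored vector.
#' @export
standardize_composite <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2) stop("need at least 2 values")
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) stop("zero variance: cannot standardize")
  (values - mean(values)) / s
}

glmm_formula <- function(fixed) {
  allowed <- c("span", "age", "span:age")
  if (!all(fixed %in% allowed))
    stop("`fixed` terms must be among: ", paste(allowed, collapse = ", "))
  rhs <- c(sub("span", "span_score", fixed, fixed = TRUE), "(1 | subject)",
           "(1 | item)")
  stats::as.formula(paste("cbind(n_correct, n_missed) ~",
                          paste(c("1", rhs), collapse = " + ")))
}

#' Fit the grouped-binomial logistic mixed model for transcription accuracy
#'
#' Per-sentence keyword outcomes are modeled as grouped binomial counts
#' (`n_correct` successes, `n_missed` failures) with a logit link, fixed
#' effects chosen from span score, age and their interaction, and crossed
#' random intercepts by subject and by item. Estimation is by Laplace
#' approximation to the marginal likelihood via [lme4::glmer()].
#'
#' @param data Data.frame with columns `subject`, `item`, `n_correct`,
#'   `n_missed`, and the covariates named by `fixed` (`span_score`, `age`).
#' @param fixed Character vector of fixed-effect terms beyond the intercept;
#'   any of `"span"`, `"age"`, `"span:age"`. Use `character(0)` for an
#'   intercept-only model.
#' @param center Center span score and age before fitting (default `FALSE`:
#'   raw scales).
#' @return A list of class `glmm_fit`: `coefficients` (estimate, SE, z),
#'   `varcomp` (subject and item intercept SDs), `loglik`, `n_fixed`,
#'   `converged`, `method`, `model` (the underlying lme4 fit).
#' @export
fit_grouped_binomial_glmm <- function(data, fixed = c("span", "age",
                                                      "span:age"),
                                      center = FALSE) {
  data <- as.data.frame(data)
  req <- c("subject", "item", "n_correct", "n_missed")
  miss <- setdiff(req, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (length(unique(data$subject)) < 2 || length(unique(data$item)) < 2)
    stop("need at least 2 subjects and 2 items")
  if (any(data$n_correct < 0 | data$n_missed < 0))
    stop("counts must be non-negative")
  if (center) {
    if ("span_score" %in% names(data))
      data$span_score <- data$span_score - mean(data$span_score)
    if ("age" %in% names(data)) data$age <- data$age - mean(data$age)
  }
  fm <- glmm_formula(fixed)
  fit <- suppressMessages(lme4::glmer(
    fm, data = data, family = stats::binomial(link = "logit"),
    control = lme4::glmerControl(check.conv.singular = "ignore",
                                 calc.derivs = FALSE)))
  conv <- length(fit@optinfo$conv$lme4$messages) == 0 &&
    fit@optinfo$conv$opt == 0
  cf <- summary(fit)$coefficients
  vc <- lme4::VarCorr(fit)
  out <- list(
    coefficients = data.frame(term = rownames(cf), estimate = cf[, 1],
                              se = cf[, 2], z = cf[, 3],
                              row.names = NULL, stringsAsFactors = FALSE),
    varcomp = c(sd_subject = attr(vc$subject, "stddev")[[1]],
                sd_item = attr(vc$item, "stddev")[[1]]),
    loglik = as.numeric(stats::logLik(fit)),
    n_fixed = nrow(cf),
    converged = conv,
    method = "Laplace approximation (lme4::glmer)",
    model = fit
  )
  class(out) <- "glmm_fit"
  out
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat("Grouped-binomial logistic mixed model —", x$method, "\n")
  cat(sprintf("logLik %.2f, converged: %s\n", x$loglik, x$converged))
  print(x$coefficients, digits = 3)
  cat(sprintf("Random intercept SDs: subject %.3f, item %.3f\n",
              x$varcomp[["sd_subject"]], x$varcomp[["sd_item"]]))
  invisible(x)
}

#' Likelihood-ratio test of nested mixed-model fits
#'
#' Chi-squared statistic 2 (logLik_full - logLik_reduced) with degrees of
#' freedom equal to the difference in fixed-effect counts. Tiny negative
#' statistics from optimizer noise are clamped at zero.
#'
#' @param full,reduced Fits from [fit_grouped_binomial_glmm()] or
#'   [fit_ratings_lmm()]; `reduced` must be nested in `full`.
#' @return List of class `lrt_result`: `chi2`, `df`, `p`.
#' @export
likelihood_ratio_test <- function(full, reduced) {
  for (f in list(full, reduced))
    if (is.null(f$loglik) || is.null(f$n_fixed))
      stop("fits must carry `loglik` and `n_fixed`")
  df <- full$n_fixed - reduced$n_fixed
  if (df < 0) stop("`reduced` has more fixed effects than `full`")
  chi2 <- 2 * (full$loglik - reduced$loglik)
  if (chi2 < 0) {
    if (chi2 < -1e-6)
      warning("negative LRT statistic (", format(chi2),
              "); models may not be nested or a fit failed")
    chi2 <- 0
  }
  p <- if (df == 0) as.numeric(chi2 <= 0) else
    stats::pchisq(chi2, df, lower.tail = FALSE)
  structure(list(chi2 = chi2, df = df, p = p), class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT: chi-squared = %.3f, df = %d, p = %.4g\n",
              x$chi2, x$df, x$p))
  invisible(x)
}

#' Fit the post-task ratings linear mixed model
#'
#' Models a standardized rating composite (affect, fatigue or motivation)
#' with fixed effects for the task just completed (dummy-coded against the
#' span-game reference level) and counterbalance order, plus a random
#' intercept by participant. Fit by maximum likelihood so that
#' likelihood-ratio tests between nested fits are valid; the task-factor LRT
#' has 4 degrees of freedom (five tasks).
#'
#' @param data Data.frame with columns `participant`, `task`,
#'   `counterbalance`, `composite`.
#' @param reference Reference task level (default `"sandwich"`).
#' @param include_task Include the task factor (set `FALSE` for the reduced
#'   model of the task LRT).
#' @return A list of class `lmm_fit` compatible with
#'   [likelihood_ratio_test()]: `coefficients`, `task_contrasts` (named
#'   vector of task effects relative to the reference), `loglik`, `n_fixed`,
#'   `converged`, `model`.
#' @export
fit_ratings_lmm <- function(data, reference = "sandwich",
                            include_task = TRUE) {
  data <- as.data.frame(data)
  req <- c("participant", "task", "counterbalance", "composite")
  miss <- setdiff(req, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  data$task <- stats::relevel(factor(data$task), ref = reference)
  data$counterbalance <- factor(data$counterbalance)
  fm <- if (include_task)
    composite ~ task + counterbalance + (1 | participant)
  else composite ~ counterbalance + (1 | participant)
  fit <- suppressMessages(lme4::lmer(
    fm, data = data, REML = FALSE,
    control = lme4::lmerControl(check.conv.singular = "ignore",
                                calc.derivs = FALSE)))
  cf <- summary(fit)$coefficients
  task_rows <- grepl("^task", rownames(cf))
  contrasts <- stats::setNames(cf[task_rows, 1],
                               sub("^task", "", rownames(cf)[task_rows]))
  out <- list(
    coefficients = data.frame(term = rownames(cf), estimate = cf[, 1],
                              se = cf[, 2], row.names = NULL,
                              stringsAsFactors = FALSE),
    task_contrasts = contrasts,
    loglik = as.numeric(stats::logLik(fit)),
    n_fixed = nrow(cf),
    converged = length(fit@optinfo$conv$lme4$messages) == 0,
    model = fit
  )
  class(out) <- "lmm_fit"
  out
}

#' Likelihood-ratio test for the task factor in the ratings model
#'
#' Convenience wrapper fitting the ratings model with and without the task
#' factor and comparing them (df = 4 for five tasks).
#'
#' @inheritParams fit_ratings_lmm
#' @return An `lrt_result`.
#' @export
ratings_task_lrt <- function(data, reference = "sandwich") {
  full <- fit_ratings_lmm(data, reference, include_task = TRUE)
  reduced <- fit_ratings_lmm(data, reference, include_task = FALSE)
  likelihood_ratio_test(full, reduced)
}
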