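#' Resampling-based power curve for the span effect
#'
#' Estimates power to detect the span-score main effect on transcription
#' accuracy at a grid of sample sizes by repeatedly drawing participants from
#' the pool and refitting the grouped-binomial mixed model. Each iteration
#' samples `n` distinct participants (without replacement by default), fits
#' the span-only model (`span_score` fixed effect, crossed subject and item
#' random intercepts — the age interaction is deliberately omitted) against
#' the intercept-only model, and records whether the span likelihood-ratio
#' test has p < `alpha`. Iterations whose fits fail to converge are excluded
#' from the power denominator and counted in `n_failed`.
#'
#' @param data Transcription pool: data.frame with `subject`, `item`,
#'   `n_correct`, `n_missed`, `span_score`.
#' @param n_grid Sample sizes to probe (default `seq(10, 150, 10)`); every
#'   value must be at most the number of distinct subjects.
#' @param iterations Resampling iterations per sample size (default 1000).
#' @param alpha Significance level (default 0.05).
#' @param seed Integer seed for the whole curve.
#' @param replace Sample participants with replacement (default `FALSE`).
#' @param ci Confidence-interval method for the power proportion:
#'   `"normal"` (default) or `"wilson"`.
#' @param conf_level Confidence level (default 0.95).
#' @return A data.frame of class `power_curve` with columns `n`, `power`,
#'   `ci_low`, `ci_high`, `iterations`, `n_failed`.
#' @export
resample_power <- function(data, n_grid = seq(10L, 150L, 10L),
                           iterations = 1000L, alpha = 0.05, seed = 1L,
                           replace = FALSE, ci = c("normal", "wilson"),
                           conf_level = 0.95) {
  ci <- match.arg(ci)
  data <- as.data.frame(data)
  req <- c("subject", "item", "n_correct", "n_missed", "span_score")
  miss <- setdiff(req, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  subjects <- unique(data$subject)
  if (!replace && any(n_grid > length(subjects)))
    stop("`n_grid` exceeds the participant pool (", length(subjects), ")")
  if (iterations < 1) stop("`iterations` must be at least 1")
  set.seed(as.integer(seed))
  rows_by_subject <- split(seq_len(nrow(data)), data$subject)
  zc <- stats::qnorm(1 - (1 - conf_level) / 2)
  out <- lapply(n_grid, function(n) {
    sig <- logical(iterations)
    ok <- logical(iterations)
    for (it in seq_len(iterations)) {
      ids <- sample(subjects, n, replace = replace)
      sub <- data[unlist(rows_by_subject[as.character(ids)],
                         use.names = FALSE), , drop = FALSE]
      res <- tryCatch({
        full <- fit_grouped_binomial_glmm(sub, fixed = "span")
        reduced <- fit_grouped_binomial_glmm(sub, fixed = character(0))
        if (!full$converged || !reduced$converged) NULL
        else likelihood_ratio_test(full, reduced)
      }, error = function(e) NULL)
      if (!is.null(res)) {
        ok[it] <- TRUE
        sig[it] <- res$p < alpha
      }
    }
    m <- sum(ok)
    p_hat <- if (m > 0) mean(sig[ok]) else NA_real_
    if (ci == "normal") {
      half <- zc * sqrt(p_hat * (1 - p_hat) / m)
      lo <- max(0, p_hat - half); hi <- min(1, p_hat + half)
    } else {
      z2 <- zc^2
      centre <- (p_hat + z2 / (2 * m)) / (1 + z2 / m)
      half <- zc * sqrt(p_hat * (1 - p_hat) / m + z2 / (4 * m^2)) /
        (1 + z2 / m)
      lo <- max(0, centre - half); hi <- min(1, centre + half)
    }
    data.frame(n = n, power = p_hat, ci_low = lo, ci_high = hi,
               iterations = m, n_failed = iterations - m)
  })
  curve <- do.call(rbind, out)
  attr(curve, "alpha") <- alpha
  attr(curve, "seed") <- seed
  class(curve) <- c("power_curve", "data.frame")
  curve
}

#' Locate the grid interval where a power curve crosses a target
#'
#' Returns the smallest consecutive grid pair `(n_low, n_high)` such that
#' `power(n_low) < target <= power(n_high)`. If the first grid point already
#' reaches the target, `n_low` is `NA` (left-open bracket); if the target is
#' never attained, `reached` is `FALSE`.
#'
#' @param curve A `power_curve` from [resample_power()] (or any data.frame
#'   with `n` and `power` columns, ordered by `n`).
#' @param target Target power (default 0.80).
#' @return List with `reached`, `n_low`, `n_high`.
#' @export
find_crossing <- function(curve, target = 0.80) {
  if (nrow(curve) == 0) stop("empty power curve")
  p <- curve$power
  n <- curve$n
  if (p[1] >= target)
    return(list(reached = TRUE, n_low = NA_integer_, n_high = n[1]))
  for (i in seq_len(length(p) - 1)) {
    if (p[i] < target && p[i + 1] >= target)
      return(list(reached = TRUE, n_low = n[i], n_high = n[i + 1]))
  }
  list(reached = FALSE, n_low = NA_integer_, n_high = NA_integer_)
}
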