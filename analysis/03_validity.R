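#!/usr/bin/env Rscript

# Stage 3 — the psychometric validation analyses.
#
# From results/scores.csv and the scored transcription tables:
#  * retest outlier screen (score differences beyond 5 mean absolute
#    deviations from the mean difference),
#  * convergent validity: Pearson correlations among the five task scores
#    with Bonferroni correction over the 10 pairs,
#  * reliability: two-way random-effects single-rater ICC (agreement form)
#    between the two staircase sessions,
#  * discriminant validity: Bayes factor for the correlation between the
#    staircase score and the extraversion composite (stretched beta prior,
#    width 1.0),
#  * predictive validity: grouped-binomial logistic mixed models of keyword
#    accuracy with crossed subject/item intercepts and likelihood-ratio
#    tests for span, age and their interaction,
#  * ratings: linear mixed models of the affect/fatigue/motivation
#    composites with task and counterbalance fixed effects.
# Writes results/correlations.csv, results/validity_report.txt.

library(gamespan)

scores <- utils::read.csv("results/scores.csv", stringsAsFactors = FALSE)
trans <- list(
  noise = utils::read.csv("results/transcription_noise.csv",
                          stringsAsFactors = FALSE),
  accent = utils::read.csv("results/transcription_accent.csv",
                           stringsAsFactors = FALSE))
extraversion <- utils::read.csv("results/extraversion.csv",
                                stringsAsFactors = FALSE)
ratings <- load_trial_table("results/data/ratings.csv", "ratings")

sink("results/validity_report.txt", split = TRUE)

sb1 <- scores[scores$task == "sandwich" & scores$session == 1, ]
sb2 <- scores[scores$task == "sandwich" & scores$session == 2, ]
sb2 <- sb2[match(sb1$participant, sb2$participant), ]
flags <- flag_retest_outliers(sb1$score, sb2$score, threshold = 5)
dropped <- sb1$participant[flags]
cat(sprintf("Retest outlier screen: %d of %d participants removed\n\n",
            length(dropped), nrow(sb1)))
keep <- !(scores$participant %in% dropped)

cat("== Convergent validity ==\n")
wide <- scores_wide(scores[keep, ])
tasks <- c("sandwich", "digit_aud", "digit_vis", "free_aud", "free_vis")
ct <- correlation_matrix(wide[, tasks], family_size = 10)
print(as.data.frame(ct), digits = 2)
utils::write.csv(as.data.frame(ct), "results/correlations.csv",
                 row.names = FALSE)

cat("\n== Reliability ==\n")
icc <- icc_two_way_random(sb1$score[!flags], sb2$score[!flags])
print(icc)

cat("\n== Discriminant validity ==\n")
ext <- extraversion[!(extraversion$participant %in% dropped), ]
s2k <- sb2[!flags, ]
r <- cor(ext$composite, s2k$score[match(ext$participant, s2k$participant)])
cat(sprintf("r(staircase score, extraversion) = %.3f\n", r))
print(bayes_cor_bf10(r, nrow(ext)))

cat("\n== Predictive validity ==\n")
for (nm in names(trans)) {
  tab <- trans[[nm]][!(trans[[nm]]$subject %in% dropped), ]
  full <- fit_grouped_binomial_glmm(tab)
  no_int <- fit_grouped_binomial_glmm(tab, fixed = c("span", "age"))
  span_only <- fit_grouped_binomial_glmm(tab, fixed = "span")
  no_span <- fit_grouped_binomial_glmm(tab, fixed = "age")
  cat(sprintf("\n-- %s transcription --\n", nm))
  print(if (nm == "accent") no_int else full)
  cat("span:        "); print(likelihood_ratio_test(no_int, no_span))
  cat("age:         "); print(likelihood_ratio_test(no_int, span_only))
  cat("span x age:  "); print(likelihood_ratio_test(full, no_int))
}

cat("\n== Post-task ratings ==\n")
ratings <- ratings[!(ratings$participant %in% dropped), ]
for (m in unique(ratings$measure)) {
  sub <- ratings[ratings$measure == m, ]
  sub$composite <- standardize_composite(sub$value)
  fit <- fit_ratings_lmm(sub)
  lrt <- ratings_task_lrt(sub)
  cat(sprintf("\n-- %s -- task LRT: chi2 = %.2f, df = %d, p = %.3g\n",
              m, lrt$chi2, lrt$df, lrt$p))
  print(round(fit$task_contrasts, 3))
}

sink()
cat("\nWrote results/validity_report.txt and results/correlations.csv\n")
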