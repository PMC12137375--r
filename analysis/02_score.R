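#!/usr/bin/env Rscript

# Stage 2 — score every task from the simulated trial tables.
#
# Reloads the CSVs written by 01_simulate.R through the schema validator
# (so this stage exercises the same path an external dataset would take),
# applies the base-plus-partial-credit rule to the staircase sessions, the
# mean-span rule to the digit-span ladders, order-free matching to free
# recall, the rule-based keyword scorer to the transcriptions, and the
# reverse-keyed mean to the extraversion items. Writes results/scores.csv,
# results/transcription_{noise,accent}.csv and results/extraversion.csv.

library(gamespan)

tables <- list(
  sandwich_s1 = load_trial_table("results/data/sandwich_s1.csv", "sandwich"),
  sandwich_s2 = load_trial_table("results/data/sandwich_s2.csv", "sandwich"),
  digit_span_aud = load_trial_table("results/data/digit_span_aud.csv",
                                    "serial_span"),
  digit_span_vis = load_trial_table("results/data/digit_span_vis.csv",
                                    "serial_span"),
  free_recall_aud = load_trial_table("results/data/free_recall_aud.csv",
                                     "free_recall"),
  free_recall_vis = load_trial_table("results/data/free_recall_vis.csv",
                                     "free_recall"),
  transcription_noise = load_trial_table(
    "results/data/transcription_noise.csv", "transcription"),
  transcription_accent = load_trial_table(
    "results/data/transcription_accent.csv", "transcription"),
  ratings = load_trial_table("results/data/ratings.csv", "ratings"),
  extraversion = load_trial_table("results/data/extraversion.csv",
                                  "extraversion")
)

scored <- score_cohort(tables)

utils::write.csv(scored$scores, "results/scores.csv", row.names = FALSE)
utils::write.csv(scored$transcription$noise,
                 "results/transcription_noise.csv", row.names = FALSE)
utils::write.csv(scored$transcription$accent,
                 "results/transcription_accent.csv", row.names = FALSE)
utils::write.csv(scored$extraversion, "results/extraversion.csv",
                 row.names = FALSE)

wide <- scores_wide(scored$scores)
cat("Per-task score means (SD), session 1:\n")
for (task in setdiff(names(wide), "participant"))
  cat(sprintf("  %-10s %.2f (%.2f)\n", task, mean(wide[[task]]),
              sd(wide[[task]])))
cat(sprintf("Scored %d participants; %d noise and %d accent sentences\n",
            nrow(wide), nrow(scored$transcription$noise),
            nrow(scored$transcription$accent)))
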