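#!/usr/bin/env Rscript

# Stage 1 — simulate the synthetic validation cohort.
#
# Generates 250 participants under the default generator configuration
# (latent capacity N(5.0, 1.4^2) on the ingredient scale, retest correlation
# 0.84, common-factor loadings calibrated to the published cross-task
# correlation pattern) and writes every trial-level table to
# results/data/ as CSV, together with a manifest of the configuration.

library(gamespan)

cfg <- generator_config(n_participants = 250L, seed = 20260101L)
profiles <- generate_cohort(cfg)
dataset <- generate_dataset(profiles, cfg)

print(dataset)

dir.create("results", showWarnings = FALSE)
paths <- write_cohort_csv(dataset, "results/data")
utils::write.csv(profiles, "results/data/profiles.csv", row.names = FALSE)

cat("\nWrote", length(paths) + 1, "files under results/data/\n")
cat(sprintf("Cohort: %d participants, ages %.0f-%.0f, counterbalance groups of %s\n",
            nrow(profiles), min(profiles$age), max(profiles$age),
            paste(unique(table(profiles$counterbalance)), collapse = "/")))
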