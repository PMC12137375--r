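#!/usr/bin/env Rscript

# Stage 5 — one-shot end-to-end run.
#
# Re-executes the whole pipeline (simulate -> score -> validate -> power)
# through run_validation_pipeline() from a single seed, demonstrating that
# the staged scripts and the orchestrated run agree, and writes the bundled
# report under results/pipeline/. A reduced power grid keeps this driver
# quick; stages 01-04 produce the full-resolution artifacts.

library(gamespan)

cfg <- generator_config(n_participants = 250L, seed = 20260101L)
bundle <- run_validation_pipeline(
  cfg,
  power_grid = c(30L, 70L, 110L),
  power_iterations = 60L,
  outdir = "results/pipeline")

print(bundle)

cat("\nArtifacts under results/pipeline/\n")
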