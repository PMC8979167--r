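#!/usr/bin/env Rscript
# Step 1: generate a study-sized synthetic annotation exercise.
#
# 18 raters view 24 larval specimens in two independent sessions: first
# reporting endpoints in their own words (Survey 1), then from the
# controlled ZP vocabulary (Survey 2). Writes the ground truth, both survey
# tables, and the lexicon/hierarchy the raters' vocabulary came from.

suppressPackageStartupMessages(library(phenoconcord))

args <- commandArgs(trailingOnly = TRUE)
seed <- as.integer(if (length(args) >= 1) args[1] else 20260930 %% 2^31)

out_dir <- "results/sim"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = seed)
sim <- generate(cfg)
print(sim)

write_survey(sim$survey1, file.path(out_dir, "survey1.tsv"))
write_survey(sim$survey2, file.path(out_dir, "survey2.tsv"))

truth <- data.frame(specimen = rownames(sim$truth_unit),
                    sim$truth_unit, check.names = FALSE)
utils::write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(sim$lexicon$table, file.path(out_dir, "lexicon.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(sim$hierarchy$table, file.path(out_dir, "hierarchy.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

message(sprintf(
  "simulated %d + %d annotations over %d specimens (seed %d) -> %s",
  nrow(sim$survey1$records), nrow(sim$survey2$records), cfg$n_specimens,
  seed, out_dir))
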