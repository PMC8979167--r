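#!/usr/bin/env Rscript
# Step 2: map free-text terms to ZP CURIEs and roll up to general traits.
#
# Reads the survey tables written by 01_simulate.R, restricts to raters who
# took both surveys, harmonizes each against the lexicon/hierarchy, and
# writes the annotated long tables plus the curation queue of any unmapped
# verbatim terms.

suppressPackageStartupMessages(library(phenoconcord))

in_dir <- "results/sim"
out_dir <- "results/harmonized"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

hierarchy <- read_trait_hierarchy(file.path(in_dir, "hierarchy.tsv"))
lexicon <- read_term_lexicon(file.path(in_dir, "lexicon.tsv"), hierarchy)
s1 <- read_survey(file.path(in_dir, "survey1.tsv"), "S1")
s2 <- read_survey(file.path(in_dir, "survey2.tsv"), "S2")

pr <- paired_raters(s1, s2)
message(length(pr), " raters took both surveys; restricting to them")
s1 <- restrict_raters(s1, pr)
s2 <- restrict_raters(s2, pr)

h1 <- harmonize_table(s1, lexicon, hierarchy)
h2 <- harmonize_table(s2, lexicon, hierarchy)
utils::write.table(h1, file.path(out_dir, "survey1_harmonized.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(h2, file.path(out_dir, "survey2_harmonized.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

queue <- curation_queue(h1)
utils::write.table(queue, file.path(out_dir, "curation_queue.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf(
  "harmonized %d + %d records; %d unmapped verbatim term(s) queued",
  nrow(h1), nrow(h2), nrow(queue)))
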