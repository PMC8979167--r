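#!/usr/bin/env Rscript
# Step 5: intraclass-correlation repeatability of concordance.
#
# One-way variance-components ICC of the binary concordance cells with
# specimen, trait, or rater as the grouping factor, per survey and per
# annotation granularity (12 estimates), with seeded bootstrap percentile
# confidence intervals.

suppressPackageStartupMessages(library(phenoconcord))

in_dir <- "results/concordance"
out_dir <- "results/repeatability"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cells <- do.call(rbind, lapply(c("general", "granular"), function(lev) {
  do.call(rbind, lapply(c("S1", "S2"), function(sv) {
    d <- utils::read.table(
      file.path(in_dir, sprintf("cells_%s_%s.tsv", lev, sv)),
      header = TRUE, sep = "\t", quote = "", stringsAsFactors = FALSE)
    cbind(d[, c("rater", "specimen", "trait", "concordant")],
          survey = sv, level = lev)
  }))
}))

tab <- icc_table(cells, B = 500, seed = 11)
utils::write.table(tab, file.path(out_dir, "icc_table.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
for (i in seq_len(nrow(tab))) {
  message(sprintf(
    "%-8s %-8s %s: ICC = %.3f [%.3f, %.3f]  (%d groups, %d obs)",
    tab$granularity[i], tab$factor[i], tab$survey[i], tab$icc[i],
    tab$ci_low[i], tab$ci_high[i], tab$n_groups[i], tab$n_obs[i]))
}
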