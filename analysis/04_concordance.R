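#!/usr/bin/env Rscript
# Step 4: majority-vote concordance and its change between surveys.
#
# Builds the binary presence tensors over the (specimen, trait) pairs
# observed in either survey, scores every rater against the majority,
# reports mean concordance by rater/specimen/trait per survey, tests
# per-unit concordance change with two-sided Fisher exact tests (BH
# column alongside), and correlates per-trait concordance with the
# heterogeneity drivers.

suppressPackageStartupMessages(library(phenoconcord))

in_dir <- "results/harmonized"
out_dir <- "results/concordance"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

read_harm <- function(f) {
  utils::read.table(file.path(in_dir, f), header = TRUE, sep = "\t",
                    quote = "", stringsAsFactors = FALSE)
}
h1 <- read_harm("survey1_harmonized.tsv")
h2 <- read_harm("survey2_harmonized.tsv")
hierarchy <- read_trait_hierarchy("results/sim/hierarchy.tsv")

all_cells <- list()
for (lev in c("general", "granular")) {
  col <- if (lev == "general") "general_curie" else "granular_curie"
  traits <- sort(union(unique(h1[[col]]), unique(h2[[col]])))
  raters <- sort(unique(h1$rater))
  specimens <- sort(union(unique(h1$specimen), unique(h2$specimen)))
  m1 <- presence_matrix(h1, lev, raters, specimens, traits)
  m2 <- presence_matrix(h2, lev, raters, specimens, traits)
  uni <- observed_universe(m1, m2)
  c1 <- concordance_cells(m1, uni)
  c2 <- concordance_cells(m2, uni)

  for (sv in c("S1", "S2")) {
    cells <- if (sv == "S1") c1 else c2
    utils::write.table(
      cells, file.path(out_dir, sprintf("cells_%s_%s.tsv", lev, sv)),
      sep = "\t", quote = FALSE, row.names = FALSE)
    for (g in c("rater", "specimen", "trait")) {
      mc <- mean_concordance(cells, g)
      utils::write.table(
        mc, file.path(out_dir, sprintf("mean_by_%s_%s_%s.tsv", g, lev, sv)),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
    mc <- mean_concordance(cells, "rater")
    message(sprintf(
      "%s %s: rater mean concordance %.1f%% +/- %.1f%%", lev, sv,
      100 * mean(mc$mean_concordance),
      100 * attr(mc, "between_group_sd")))
  }

  for (u in c("trait", "rater", "rater_trait")) {
    ch <- concordance_change(c1, c2, unit = u)
    utils::write.table(
      ch, file.path(out_dir, sprintf("change_by_%s_%s.tsv", u, lev)),
      sep = "\t", quote = FALSE, row.names = FALSE)
    sig <- ch[ch$p_value < 0.05, ]
    message(sprintf(
      "%s level, unit %s: %d/%d units changed significantly (raw p < 0.05)",
      lev, u, nrow(sig), nrow(ch)))
  }
  all_cells[[lev]] <- list(s1 = c1, s2 = c2)
}

# per-trait concordance vs heterogeneity drivers (general level)
s <- summarize_survey(h1, hierarchy, level = "general")
both <- rbind(all_cells$general$s1, all_cells$general$s2)
mt <- mean_concordance(both, "trait")
m <- merge(mt, s, by.x = "group", by.y = "trait")
cors <- data.frame(
  pair = c("mean_concordance~unique_terms", "mean_concordance~n_specimens"),
  pearson_r = c(pearson_r(m$mean_concordance, m$unique_terms),
                pearson_r(m$mean_concordance, m$n_specimens)))
utils::write.table(cors, file.path(out_dir, "trait_correlations.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf(
  "concordance vs unique terms: r = %.2f; vs specimens showing trait: r = %.2f",
  cors$pearson_r[1], cors$pearson_r[2]))
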