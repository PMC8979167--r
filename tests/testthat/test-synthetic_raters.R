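test_that("generation is fully determined by the seed", {
  cfg <- sim_config(n_raters = 6, n_specimens = 8, seed = 99)
  expect_identical(generate(cfg), generate(cfg))
  other <- generate(sim_config(n_raters = 6, n_specimens = 8, seed = 100))
  expect_false(identical(generate(cfg)$survey1$records, other$survey1$records))
})

test_that("simulator output is internally consistent with its own lexicon", {
  sim <- generate(sim_config(n_raters = 6, n_specimens = 8, seed = 4))
  h1 <- harmonize_table(sim$survey1, sim$lexicon, sim$hierarchy)
  expect_equal(sum(is.na(h1$granular_curie)), 0L)   # full mapping coverage
  catalog_ids <- names(sim$config$catalog$synonyms)
  expect_true(all(sim$survey2$records$term %in% c(catalog_ids, "normal")))
  expect_true(all(dim(sim$truth_unit) ==
                    c(8, nrow(sim$config$catalog$units))))
})

test_that("error-free raters reproduce the truth in both surveys", {
  cfg <- sim_config(n_raters = 5, n_specimens = 10, sensitivity = 1,
                    specificity = 1, p_general = 0, choice_error = 0,
                    rater_effect_sd = 0,
                    catalog = default_trait_catalog(n_synonyms = 1),
                    seed = 12)
  sim <- generate(cfg)
  h1 <- harmonize_table(sim$survey1, sim$lexicon, sim$hierarchy)
  h2 <- harmonize_table(sim$survey2, sim$lexicon, sim$hierarchy)
  pc <- paired_cells(h1, h2, "granular")
  expect_identical(pc$m1[, , ], pc$m2[, , ])
  expect_equal(mean(pc$s1$concordant), 1)
  expect_equal(mean(pc$s2$concordant), 1)
  # every rater's presence row equals the truth for the observed units
  units <- intersect(dimnames(pc$m1)$trait, colnames(sim$truth_unit))
  for (r in dimnames(pc$m1)$rater) {
    expect_equal(unname(pc$m1[r, rownames(sim$truth_unit), units]),
                 unname(sim$truth_unit[, units]))
  }
})

test_that("larger synonym pools yield more unique terms", {
  uniq <- vapply(c(1, 3, 6), function(k) {
    cfg <- sim_config(n_raters = 10, n_specimens = 20,
                      catalog = default_trait_catalog(n_synonyms = k),
                      idiolect_size = 3, seed = 31)
    sim <- generate(cfg)
    h1 <- harmonize_table(sim$survey1, sim$lexicon, sim$hierarchy)
    length(unique(h1$term_norm))
  }, numeric(1))
  expect_true(all(diff(uniq) > 0))
})

test_that("lower sensitivity lowers mean rater concordance", {
  mean_conc <- vapply(c(0.95, 0.75, 0.55), function(sens) {
    out <- vapply(1:3, function(sd) {
      cfg <- sim_config(n_raters = 10, n_specimens = 16,
                        sensitivity = sens, rater_effect_sd = 0,
                        seed = 100 + sd)
      sim <- generate(cfg)
      h1 <- harmonize_table(sim$survey1, sim$lexicon, sim$hierarchy)
      h2 <- harmonize_table(sim$survey2, sim$lexicon, sim$hierarchy)
      pc <- paired_cells(h1, h2, "general")
      mean(pc$s1$concordant)
    }, numeric(1))
    mean(out)
  }, numeric(1))
  expect_true(all(diff(mean_conc) < 0))
})

test_that("one low-sensitivity rater shows the lowest mean concordance", {
  sens <- c(0.6, rep(0.95, 9))
  cfg <- sim_config(n_raters = 10, n_specimens = 20, sensitivity = sens,
                    rater_effect_sd = 0, seed = 8)
  sim <- generate(cfg)
  h1 <- harmonize_table(sim$survey1, sim$lexicon, sim$hierarchy)
  h2 <- harmonize_table(sim$survey2, sim$lexicon, sim$hierarchy)
  pc <- paired_cells(h1, h2, "general")
  both <- rbind(pc$s1, pc$s2)
  mc <- mean_concordance(both, "rater")
  expect_equal(mc$group[which.min(mc$mean_concordance)], "R01")
})

test_that("parameter recovery flags realized rates near their targets", {
  cfg <- sim_config(n_raters = 8, n_specimens = 200,
                    specimen_effect_sd = 0, seed = 17)
  sim <- generate(cfg)
  rp <- recover_parameters(sim)
  expect_true(all(c("prevalence", "sensitivity", "false_tag_rate",
                    "unique_terms_within_pool") %in% rp$check))
  prev <- rp[rp$check == "prevalence", ]
  expect_true(all(abs(prev$observed - prev$expected) <= prev$tol))
  expect_true(all(rp$pass[rp$check == "unique_terms_within_pool"]))
  expect_gte(mean(rp$pass), 0.95)
})

test_that("zero rater effect leaves no rater-level repeatability", {
  cfg <- sim_config(n_raters = 12, n_specimens = 24, rater_effect_sd = 0,
                    seed = 23)
  sim <- generate(cfg)
  h1 <- harmonize_table(sim$survey1, sim$lexicon, sim$hierarchy)
  h2 <- harmonize_table(sim$survey2, sim$lexicon, sim$hierarchy)
  pc <- paired_cells(h1, h2, "general")
  icc <- icc_anova(pc$s1$concordant, pc$s1$rater)$icc
  expect_lte(icc, 0.02)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(sensitivity = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(n_raters = 1), "2 raters")
  expect_error(sim_config(rater_effect_sd = -1), ">= 0")
  expect_error(sim_config(sensitivity = c(0.9, 0.8)), "per rater")
})
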