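test_that("presence matrices are binary, idempotent, and OR-aggregate upward", {
  h <- toy_hierarchy(); lx <- toy_lexicon(h)
  tab <- toy_survey(data.frame(rater = c("A", "A", "B"),
                               specimen = c("L1", "L2", "L1"),
                               term = c("curved tail", "short tail",
                                        "snout off")))
  harm <- harmonize_table(tab, lx, h)
  m <- presence_matrix(harm, "granular")
  expect_true(all(m %in% 0:1))
  expect_equal(m["A", "L1", "ZP:0010319"], 1L)
  expect_equal(m["B", "L1", "ZP:0010319"], 0L)
  expect_identical(m, presence_matrix(harm, "granular"))

  # a set granular cell implies the corresponding general cell is set
  mg <- presence_matrix(harm, "general")
  for (child in c("ZP:0010319", "ZP:0001130")) {
    if (!child %in% dimnames(m)$trait) next
    parent <- generalize(child, h)
    expect_true(all(mg[, , parent] >= m[, , child]))
  }
  expect_error(presence_matrix(harm[0, ], "general"), "no mapped")
})

test_that("majority needs a strict majority; ties resolve to absent", {
  m <- pattern_matrix(c(1, 1, 1, 0, 0))
  expect_equal(majority_call(m, "s1", "T"), 1L)
  expect_equal(majority_call(pattern_matrix(c(1, 1, 0, 0)), "s1", "T"), 0L)
  expect_equal(majority_call(pattern_matrix(rep(1, 4)), "s1", "T"), 1L)
  expect_equal(majority_call(pattern_matrix(rep(0, 4)), "s1", "T"), 0L)
  expect_message(
    cells <- concordance_cells(pattern_matrix(c(1, 1, 0, 0))),
    "tied")
  expect_equal(unique(cells$majority), 0L)
  expect_message(
    dropped <- concordance_cells(pattern_matrix(c(1, 1, 0, 0)),
                                 tie = "drop"),
    "dropped")
  expect_equal(nrow(dropped), 0L)
})

test_that("concordant counts equal max(k, n-k) for every rating pattern up to n = 5", {
  uni <- data.frame(specimen = "s1", trait = "T")
  for (n in 2:5) {
    patterns <- expand.grid(rep(list(0:1), n))
    for (i in seq_len(nrow(patterns))) {
      bits <- as.integer(patterns[i, ])
      k <- sum(bits)
      cells <- suppressMessages(
        concordance_cells(pattern_matrix(bits), universe = uni))
      expected <- if (2 * k == n) n - k else max(k, n - k)
      expect_equal(sum(cells$concordant), expected)
    }
  }
})

test_that("mean concordance aggregates by group and is label-invariant", {
  cells <- data.frame(rater = c("A", "A", "A", "A", "B", "B"),
                      specimen = "s", trait = "T",
                      concordant = c(1, 1, 0, 1, 1, 1))
  mc <- mean_concordance(cells, "rater")
  expect_equal(mc$mean_concordance[mc$group == "A"], 0.75)
  expect_equal(mc$mean_concordance[mc$group == "B"], 1)
  # pooled mean is the size-weighted mean of group means
  expect_equal(attr(mc, "pooled_mean"),
               sum(mc$n_cells * mc$mean_concordance) / sum(mc$n_cells))
  # relabeling raters leaves the sorted means unchanged
  relab <- cells; relab$rater <- chartr("AB", "ZQ", relab$rater)
  mc2 <- mean_concordance(relab, "rater")
  expect_equal(sort(mc2$mean_concordance), sort(mc$mean_concordance))

  all1 <- cells; all1$concordant <- 1
  mc3 <- mean_concordance(all1, "rater")
  expect_true(all(mc3$mean_concordance == 1))
  expect_equal(attr(mc3, "between_group_sd"), 0)
  expect_error(mean_concordance(cells, "larva"))
})

test_that("pooled mean equals the size-weighted mean of group means on random tables", {
  set.seed(9)
  for (i in 1:10) {
    n <- sample(20:100, 1)
    cells <- data.frame(
      rater = sample(LETTERS[1:5], n, replace = TRUE),
      specimen = sample(c("s1", "s2", "s3"), n, replace = TRUE),
      trait = sample(c("T1", "T2"), n, replace = TRUE),
      concordant = rbinom(n, 1, 0.8))
    for (g in c("rater", "specimen", "trait")) {
      mc <- mean_concordance(cells, g)
      expect_equal(attr(mc, "pooled_mean"),
                   sum(mc$n_cells * mc$mean_concordance) / sum(mc$n_cells))
    }
  }
})

test_that("between-survey change counts, deltas, and exact tests behave", {
  mk_cells <- function(conc) {
    data.frame(rater = "A", specimen = sprintf("L%02d", seq_along(conc)),
               trait = "T", concordant = conc)
  }
  c1 <- mk_cells(c(rep(1, 20), rep(0, 4)))
  c2 <- mk_cells(c(rep(1, 22), rep(0, 2)))
  ch <- concordance_change(c1, c2, unit = "rater")
  expect_equal(ch$delta, 2)
  expect_equal(ch$n_concordant_s1, 20)
  expect_equal(ch$mean_s2, 22 / 24)
  expect_true(abs(ch$delta) <= 24)

  same <- concordance_change(c1, c1, unit = "rater")
  expect_equal(same$delta, 0)
  expect_equal(same$p_value, 1)

  c3 <- mk_cells(c(rep(1, 20), rep(0, 4)))
  c3$specimen <- paste0("X", c3$specimen)
  expect_error(concordance_change(c1, c3, unit = "rater"), "specimen")
})

test_that("the exact test matches enumeration values and the stats oracle", {
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2, byrow = TRUE)), 1)
  # [[10,0],[0,10]]: only the two extreme tables qualify, each 1/choose(20,10)
  expect_equal(fisher_exact_2x2(matrix(c(10, 0, 0, 10), 2, byrow = TRUE)),
               2 / choose(20, 10))
  expect_equal(fisher_exact_2x2(matrix(c(1, 9, 11, 3), 2, byrow = TRUE)),
               fisher.test(matrix(c(1, 9, 11, 3), 2, byrow = TRUE))$p.value)
  expect_equal(fisher_exact_2x2(matrix(c(0, 0, 3, 7), 2, byrow = TRUE)), 1)
  set.seed(21)
  for (i in 1:200) {
    tab <- matrix(rpois(4, sample(1:8, 1)), 2)
    expect_equal(fisher_exact_2x2(tab), fisher.test(tab)$p.value,
                 tolerance = 1e-12)
  }
  expect_error(fisher_exact_2x2(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
})

test_that("pearson correlation honours its preconditions and hand values", {
  expect_equal(pearson_r(1:3, c(2, 4, 6)), 1)
  expect_equal(pearson_r(1:3, c(3, 2, 1)), -1)
  expect_equal(pearson_r(1:4, c(1, 3, 2, 4)), 0.8)
  expect_error(pearson_r(1:3, c(1, 1, 1)), "zero variance")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
  expect_error(pearson_r(1:3, 1:4), "equal length")
})
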