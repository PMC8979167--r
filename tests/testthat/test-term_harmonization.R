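test_that("normalization case-folds, squeezes whitespace, strips trailing punctuation", {
  expect_equal(normalize_term("  Curved  Tail."), "curved tail")
  expect_equal(normalize_term("C-tail"), "c-tail")
  expect_equal(normalize_term("YSE!!"), "yse")
  expect_equal(normalize_term(""), "")
  expect_equal(normalize_term("tail \t bending ; "), "tail bending")
})

test_that("normalization is idempotent on random strings", {
  set.seed(11)
  alphabet <- c(letters, LETTERS, " ", "  ", "\t", "-", ".", ",", ";", "!")
  for (i in 1:200) {
    x <- paste(sample(alphabet, sample(0:15, 1), replace = TRUE),
               collapse = "")
    expect_identical(normalize_term(normalize_term(x)), normalize_term(x))
  }
})

test_that("the packaged lexicon maps published verbatim spellings to their CURIEs", {
  lx <- zp_lexicon()
  expect_equal(map_verbatim("C-tail", lx), "ZP:0010319")
  expect_equal(map_verbatim("cfin", lx), "ZP:0004969")
  expect_equal(map_verbatim("Malformation tail", lx), "ZP:0001129")
  expect_true(is.na(map_verbatim("zzz nonsense", lx)))
  # lookup is on normalized keys
  expect_equal(map_verbatim("  CURVED  TAIL. ", lx), "ZP:0010319")
})

test_that("roll-up returns the general parent; generals and specials are fixed points", {
  h <- zp_hierarchy()
  expect_equal(generalize("ZP:0010319", h), "ZP:0001129")
  expect_equal(generalize("ZP:0004969", h), "ZP:0001129")
  expect_equal(generalize("ZP:0001129", h), "ZP:0001129")
  expect_equal(generalize(c("normal", "hatched"), h), c("normal", "hatched"))
  expect_error(generalize("ZP:9999999", h), "ZP:9999999")
})

test_that("hierarchy validation rejects orphan parents and depth > 1", {
  expect_error(trait_hierarchy(data.frame(
    granular_curie = "ZP:1", general_curie = "ZP:2", label = "x")),
    "self-parented")
  expect_error(trait_hierarchy(data.frame(
    granular_curie = c("ZP:1", "ZP:2", "ZP:3"),
    general_curie = c("ZP:2", "ZP:3", "ZP:3"),
    label = c("a", "b", "c"))),
    "depth")
})

test_that("harmonization annotates every record without losing rows", {
  h <- zp_hierarchy(); lx <- zp_lexicon()
  tab <- toy_survey(data.frame(
    rater = c("A", "A", "B", "B"),
    specimen = "L1",
    term = c("malformation tail", "short tail", "Curved tail",
             "unheard-of endpoint")))
  out <- harmonize_table(tab, lx, h)
  expect_equal(nrow(out), 4L)
  expect_equal(out$granular_curie[out$term_norm == "malformation tail"],
               "ZP:0001129")
  expect_equal(out$general_curie[out$term_norm == "malformation tail"],
               "ZP:0001129")
  expect_equal(out$granular_curie[out$term_norm == "short tail"],
               "ZP:0001130")
  expect_equal(out$general_curie[out$term_norm == "short tail"],
               "ZP:0001129")
  # unmapped is a value that lands in the curation queue, not a dropped row
  expect_true(is.na(out$granular_curie[out$term_norm ==
                                         "unheard-of endpoint"]))
  q <- curation_queue(out)
  expect_equal(q$term_norm, "unheard-of endpoint")
  expect_equal(sum(!is.na(out$granular_curie)) + sum(is.na(out$granular_curie)),
               nrow(out))
})

test_that("Survey 2 records validate against the hierarchy and resolve 'dead'", {
  h <- zp_hierarchy(); lx <- zp_lexicon()
  tab <- toy_survey(data.frame(rater = c("A", "B"), specimen = "L1",
                               term = c("ZP:0010319", "dead")), "S2")
  out <- harmonize_table(tab, lx, h)
  expect_equal(out$granular_curie, c("ZP:0010319", "ZP:0000306"))
  expect_equal(out$general_curie, c("ZP:0001129", "ZP:0000306"))
  bad <- toy_survey(data.frame(rater = "A", specimen = "L1",
                               term = "ZP:4242424"), "S2")
  expect_error(harmonize_table(bad, lx, h), "ZP:4242424")
})

test_that("mapping then roll-up commutes with a pre-collapsed general lexicon", {
  h <- zp_hierarchy(); lx <- zp_lexicon()
  collapsed <- term_lexicon(data.frame(
    verbatim = lx$table$verbatim,
    curie = generalize(lx$table$curie, h),
    stringsAsFactors = FALSE), h)
  for (v in lx$table$verbatim) {
    expect_equal(generalize(map_verbatim(v, lx), h),
                 map_verbatim(v, collapsed))
  }
})

test_that("conflicting lexicon entries error; consistent duplicates collapse", {
  expect_error(term_lexicon(data.frame(
    verbatim = c("Curved tail", "curved  TAIL"),
    curie = c("ZP:0010319", "ZP:0001130"))),
    "conflicting")
  lx <- term_lexicon(data.frame(
    verbatim = c("Curved tail", "curved  TAIL."),
    curie = c("ZP:0010319", "ZP:0010319")))
  expect_length(lx$entries, 1L)
})
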