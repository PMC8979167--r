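Package: phenoconcord
Title: Inter-Rater Concordance and Repeatability of Ontology-Harmonized
    Phenotype Annotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing multi-rater phenotype annotation surveys in
    which free-text endpoint descriptions are harmonized to Zebrafish
    Phenotype Ontology (ZP) terms. Provides readers and validators for
    long-format annotation tables, normalization and lexicon-based mapping of
    verbatim terms to granular ZP CURIEs with roll-up to general traits,
    per-trait terminology-heterogeneity metrics (terms per tag, terms per
    trait), majority-vote concordance statistics with between-survey change
    tests (two-sided Fisher exact), variance-components intraclass
    correlation (repeatability) with bootstrap confidence intervals, and a
    seeded generative simulator of multi-rater annotation surveys for
    validating every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
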