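# phenoconcord

Inter-rater concordance and repeatability of ontology-harmonized phenotype
annotations.

## The problem

Zebrafish (*Danio rerio*) toxicology screens record larval malformations —
curved tails, pericardial edema, uninflated swim bladders — but every
laboratory has its own vocabulary for them. When many raters annotate the
same larval images, the same endpoint surfaces as "C-tail", "bent tail
tip", or "abnormal tail curvature", which makes cross-laboratory data
integration nearly impossible. One remedy is to harmonize free-text
endpoint reports onto a controlled vocabulary, the Zebrafish Phenotype
Ontology (ZP), whose terms carry CURIE identifiers (e.g. `ZP:0001129`,
"abnormal tail") and sit in a two-level general/granular hierarchy.

`phenoconcord` implements the statistical pipeline for evaluating whether
that harmonization actually improves agreement, for biostatisticians and
ontology curators analysing multi-rater annotation surveys:

1. **Annotation IO** — long-format (survey, rater, specimen, term) tables,
   validation, pairing of raters across surveys.
2. **Term harmonization** — string normalization, exact lexicon lookup of
   verbatim terms onto granular ZP CURIEs, roll-up to general traits, and
   a curation queue for unmapped terms.
3. **Heterogeneity** — per-trait *terms per tag* `u/t` (unique verbatim
   strings `u` over total tags `t`; > 0.5 heterogeneous, < 0.15
   homogeneous) and *terms per trait* `u/(1 + c)` over the `c` granular
   children, with half-up rounding at the published precisions.
4. **Concordance** — majority-vote agreement: for each (specimen, trait)
   tagged by anyone, a rater is concordant when their binary call equals
   the strict majority; grouped means, between-survey change
   `delta = c2 − c1`, and two-sided Fisher exact tests on
   `[[c1, d1], [c2, d2]]`.
5. **Repeatability** — one-way variance-components ICC(1) on the 0/1
   observations: `ICC = s2_between / (s2_between + s2_within)` with
   `s2_between = max(0, (MSB − MSW)/k0)`, plus seeded bootstrap percentile
   confidence intervals.
6. **Synthetic raters** — a seeded generative model (true trait sets with
   specimen effects, per-rater sensitivity/specificity with logit rater
   effects, per-rater synonym idiolects, general-vs-granular reporting
   preference, controlled-vocabulary choice error) so every stage is
   testable without the original survey data.

## Worked example

The `analysis/` scripts run the whole pipeline on a simulated
study-sized exercise (18 raters × 24 specimens, per-trait prevalences
taken from the published per-trait specimen counts):

```sh
Rscript analysis/01_simulate.R        # synthetic surveys -> results/sim/
Rscript analysis/02_harmonize.R       # term mapping + roll-up
Rscript analysis/03_heterogeneity.R   # per-trait summary tables
Rscript analysis/04_concordance.R     # majority-vote concordance + change
Rscript analysis/05_repeatability.R   # ICC table with bootstrap CIs
```

Step 4 prints, for the default seed:

```
general S1: rater mean concordance 88.3% +/- 3.9%
general S2: rater mean concordance 89.1% +/- 3.6%
granular S1: rater mean concordance 81.0% +/- 1.3%
granular S2: rater mean concordance 91.4% +/- 1.9%
concordance vs unique terms: r = -0.51; vs specimens showing trait: r = -0.90
```

Read: at the granular level the controlled vocabulary removes the synonym
noise of the free-text survey, so mean rater concordance rises sharply; at
the general level (where roll-up already absorbs wording differences) the
gain is small. Traits described with more unique strings, and traits seen
on more specimens, have lower mean concordance — the negative Pearson
correlations. Step 5's 12-row table shows that specimen, trait, and rater
groupings each explain only a few percent of concordance variance
(ICC ≈ 0.00–0.05 with tight bootstrap intervals), i.e. discordance is
spread across the design rather than driven by a few bad images or raters.

In code, the core loop is:

```r
library(phenoconcord)
h  <- zp_hierarchy()                 # 21 general + 27 granular ZP traits
lx <- zp_lexicon()                   # published verbatim -> CURIE mappings
map_verbatim("C-tail", lx)           # "ZP:0010319" (abnormally curved tail)
generalize("ZP:0010319", h)          # "ZP:0001129" (abnormal tail)
terms_per_tag(33, 79)                # 0.42 -> "intermediate"
fisher_exact_2x2(matrix(c(20, 4, 22, 2), 2, byrow = TRUE))  # 0.6662
```

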