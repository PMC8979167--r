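#' Round half away from zero
#'
#' Commercial ("half-up") rounding: exact halves round up. Used for the
#' published summary-table precisions, where e.g. 7.5 prints as 8 and 8.5
#' as 9 — base `round()`'s round-half-even would give 8 in both cases. A
#' tiny epsilon guards ratios of integers (e.g. 7/40) against binary
#' representation pushing an exact half just below it.
#'
#' @param x numeric vector (non-negative in this package's use).
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5 + 1e-9) / p
}

#' Terms per tag: terminology heterogeneity of a trait
#'
#' The number of unique verbatim strings used for a trait divided by the
#' number of times the trait was tagged across all specimens and raters,
#' reported to 2 decimals (half-up). 1.0 means every tag used a different
#' string; values near 0 mean raters converge on shared wording.
#'
#' @param unique_terms count of distinct verbatim strings (>= 1).
#' @param total_tags count of annotations of the trait (>= 1).
#' @return ratio in (0, 1], rounded to 2 decimals.
#' @examples
#' terms_per_tag(33, 79)  # 0.42
#' @export
terms_per_tag <- function(unique_terms, total_tags) {
  if (any(total_tags < 1)) stop("terms_per_tag undefined for total_tags = 0")
  if (any(unique_terms < 1)) stop("unique_terms must be >= 1")
  if (any(unique_terms > total_tags)) {
    stop("unique_terms cannot exceed total_tags")
  }
  round_half_up(unique_terms / total_tags, 2)
}

#' Terms per trait: unique strings per catalog slot
#'
#' The number of unique verbatim strings divided by the number of general
#' and granular traits in the family (1 general + `child_traits` children),
#' rounded half-up to an integer.
#'
#' @param unique_terms count of distinct verbatim strings (>= 1).
#' @param child_traits count of granular children (>= 0).
#' @return integer ratio.
#' @examples
#' terms_per_trait(22, 4)  # 22/5 = 4.4 -> 4
#' terms_per_trait(30, 3)  # 30/4 = 7.5 -> 8
#' @export
terms_per_trait <- function(unique_terms, child_traits) {
  if (any(unique_terms < 1)) stop("unique_terms must be >= 1")
  if (any(child_traits < 0)) stop("child_traits must be >= 0")
  as.integer(round_half_up(unique_terms / (1 + child_traits), 0))
}

#' Classify a terms-per-tag value
#'
#' Values above 0.5 indicate a high degree of heterogeneity in how raters
#' describe the trait; values below 0.15 a high degree of homogeneity.
#' Boundary values are intermediate (strict inequalities).
#'
#' @param tpt terms-per-tag ratio(s) in (0, 1].
#' @return character vector: `"heterogeneous"`, `"intermediate"` or
#'   `"homogeneous"`.
#' @export
classify_heterogeneity <- function(tpt) {
  if (any(is.na(tpt)) || any(tpt <= 0) || any(tpt > 1)) {
    stop("terms-per-tag must lie in (0, 1]")
  }
  ifelse(tpt > 0.5, "heterogeneous",
         ifelse(tpt < 0.15, "homogeneous", "intermediate"))
}

#' Per-trait terminology summary of a harmonized survey
#'
#' One row per trait observed at the requested level, aggregating over all
#' raters and specimens: total tags, unique verbatim strings, granular
#' children observed, specimens tagged at least once, the two
#' heterogeneity ratios, and the heterogeneity class. Tags of a granular
#' child count toward the general trait's totals at the general level.
#' Unmapped records are excluded (with a message).
#'
#' @param harmonized a [harmonize_table()] result.
#' @param hierarchy a [trait_hierarchy()] (used for labels and child sets).
#' @param level `"general"` or `"granular"`.
#' @param uniques count distinct strings on `"normalized"` (default) or
#'   `"raw"` verbatim spellings. Survey 2 records have no verbatim text, so
#'   distinctness there is on trait ids either way.
#' @return data.frame with columns `trait`, `label`, `total_tags`,
#'   `unique_terms`, `child_traits`, `n_specimens`, `terms_per_tag`,
#'   `terms_per_trait`, `het_class`, sorted by label.
#' @export
summarize_survey <- function(harmonized, hierarchy,
                             level = c("general", "granular"),
                             uniques = c("normalized", "raw")) {
  level <- match.arg(level)
  uniques <- match.arg(uniques)
  stopifnot(inherits(hierarchy, "trait_hierarchy"))
  h <- harmonized
  un <- is.na(h$granular_curie)
  if (any(un)) {
    message(sum(un), " unmapped record(s) excluded from the trait summary")
    h <- h[!un, , drop = FALSE]
  }
  if (nrow(h) == 0L) stop("no mapped records to summarize")
  trait <- if (level == "general") h$general_curie else h$granular_curie
  ustr <- if (uniques == "raw" && !all(is.na(h$verbatim))) h$verbatim else
    h$term_norm
  sp <- split(seq_len(nrow(h)), trait)
  rows <- lapply(names(sp), function(tr) {
    i <- sp[[tr]]
    total <- length(i)
    uniq <- length(unique(ustr[i]))
    children <- if (level == "general") {
      length(setdiff(unique(h$granular_curie[i]), tr))
    } else 0L
    data.frame(
      trait = tr,
      label = unname(hierarchy$labels[tr]),
      total_tags = total,
      unique_terms = uniq,
      child_traits = children,
      n_specimens = length(unique(h$specimen[i])),
      terms_per_tag = terms_per_tag(uniq, total),
      terms_per_trait = terms_per_trait(uniq, children),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  # classify on the exact ratio: the 2-dp report can round a heavily tagged
  # trait down to 0.00, outside the classifier's domain
  out$het_class <- classify_heterogeneity(out$unique_terms / out$total_tags)
  out <- out[order(out$label, out$trait), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Packaged published per-trait count table
#'
#' The free-text survey's analytical summary counts (per general trait:
#' total tags, unique terms, granular children, specimens tagged) together
#' with the printed two heterogeneity ratios for cross-checking
#' recomputation. The whole-specimen `hatched` row has no child/specimen
#' counts published.
#'
#' @return data.frame with columns `label`, `curie`, `total_tags`,
#'   `unique_terms`, `child_traits`, `n_specimens`, `terms_per_tag_printed`,
#'   `terms_per_trait_printed`.
#' @export
survey1_trait_counts <- function() {
  path <- system.file("extdata", "survey1_trait_counts.tsv",
                      package = "phenoconcord", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    comment.char = "#", stringsAsFactors = FALSE,
                    na.strings = "NA", fileEncoding = "UTF-8")
}
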