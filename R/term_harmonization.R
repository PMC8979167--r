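#' Normalize a verbatim endpoint string
#'
#' Case-folds, strips leading/trailing whitespace, collapses internal runs
#' of whitespace to single spaces, and removes trailing sentence
#' punctuation. Idempotent: `normalize_term(normalize_term(x))` equals
#' `normalize_term(x)`. Hyphens and internal punctuation are preserved
#' ("C-tail" stays "c-tail").
#'
#' @param x character vector of verbatim terms.
#' @return normalized character vector of the same length.
#' @examples
#' normalize_term("  Curved  Tail.")
#' @export
normalize_term <- function(x) {
  x <- as.character(x)
  x <- gsub("[[:space:]]+", " ", x)
  x <- trimws(x)
  x <- sub("[.,;:!?]+$", "", x)
  x <- trimws(x)
  tolower(x)
}

#' Construct a trait hierarchy
#'
#' The two-level general/granular trait scheme: every granular CURIE has
#' exactly one general parent and general traits are their own parent
#' (depth 1, no cycles). Special non-CURIE categories (`normal`, `hatched`)
#' are self-parented pseudo-traits.
#'
#' @param df data.frame with columns `granular_curie`, `general_curie`,
#'   `label` (optional `provenance`).
#' @return object of class `trait_hierarchy`: list with `parent` (named
#'   character: trait -> general), `labels`, `generals` (CURIE generals),
#'   `granulars`, `specials`, and the source `table`.
#' @export
trait_hierarchy <- function(df) {
  need <- c("granular_curie", "general_curie", "label")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    stop("hierarchy missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df$granular_curie <- as.character(df$granular_curie)
  df$general_curie <- as.character(df$general_curie)
  if (anyDuplicated(df$granular_curie)) {
    stop("hierarchy: duplicated trait id(s): ",
         paste(unique(df$granular_curie[duplicated(df$granular_curie)]),
               collapse = ", "))
  }
  parent <- stats::setNames(df$general_curie, df$granular_curie)
  # all parents must themselves be self-parented rows (depth <= 1, acyclic)
  not_listed <- setdiff(unique(df$general_curie), df$granular_curie)
  if (length(not_listed) > 0L) {
    stop("hierarchy: general trait(s) lack a self-parented row: ",
         paste(not_listed, collapse = ", "))
  }
  grandparent <- unname(parent[parent])
  if (!all(grandparent == unname(parent))) {
    stop("hierarchy: depth exceeds one level (general traits must map to ",
         "themselves)")
  }
  is_self <- df$granular_curie == df$general_curie
  structure(
    list(parent = parent,
         labels = stats::setNames(as.character(df$label), df$granular_curie),
         generals = df$granular_curie[is_self & is_curie(df$granular_curie)],
         granulars = df$granular_curie[!is_self],
         specials = df$granular_curie[is_self & !is_curie(df$granular_curie)],
         table = df),
    class = "trait_hierarchy")
}

#' @export
print.trait_hierarchy <- function(x, ...) {
  cat(sprintf("<trait_hierarchy: %d general, %d granular, %d special>\n",
              length(x$generals), length(x$granulars), length(x$specials)))
  invisible(x)
}

#' Read a trait hierarchy TSV
#'
#' Expected columns: `granular_curie`, `general_curie`, `label`
#' (optionally `provenance`). `#` lines are comments.
#'
#' @param path TSV path.
#' @return a [trait_hierarchy()].
#' @export
read_trait_hierarchy <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = "character", fileEncoding = "UTF-8")
  trait_hierarchy(df)
}

#' Construct a term lexicon
#'
#' Maps normalized verbatim endpoint strings to granular (or general)
#' CURIEs. Keys are stored normalized via [normalize_term()]; verbatim
#' spellings that normalize to the same key must agree on the target CURIE
#' (conflicts are an error; consistent duplicates collapse silently).
#'
#' @param df data.frame with columns `verbatim`, `curie` (optional
#'   `provenance`).
#' @param hierarchy optional [trait_hierarchy()]; when given, every target
#'   CURIE must be a known trait.
#' @return object of class `term_lexicon`: list with `entries` (named
#'   character: normalized verbatim -> CURIE), `provenance`, `table`.
#' @export
term_lexicon <- function(df, hierarchy = NULL) {
  need <- c("verbatim", "curie")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    stop("lexicon missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  key <- normalize_term(df$verbatim)
  curie <- as.character(df$curie)
  prov <- if ("provenance" %in% names(df)) as.character(df$provenance) else
    rep(NA_character_, nrow(df))
  conflict <- tapply(curie, key, function(v) length(unique(v)) > 1L)
  if (any(conflict)) {
    stop("lexicon: conflicting targets for normalized key(s): ",
         paste(names(conflict)[conflict], collapse = ", "))
  }
  keep <- !duplicated(key)
  entries <- stats::setNames(curie[keep], key[keep])
  if (!is.null(hierarchy)) {
    unknown <- setdiff(unique(entries), names(hierarchy$parent))
    if (length(unknown) > 0L) {
      stop("lexicon target(s) absent from hierarchy: ",
           paste(unknown, collapse = ", "))
    }
  }
  structure(
    list(entries = entries,
         provenance = stats::setNames(prov[keep], key[keep]),
         table = df),
    class = "term_lexicon")
}

#' @export
print.term_lexicon <- function(x, ...) {
  cat(sprintf("<term_lexicon: %d normalized keys -> %d traits>\n",
              length(x$entries), length(unique(x$entries))))
  invisible(x)
}

#' Read a term lexicon TSV
#'
#' Expected columns: `verbatim`, `curie` (optionally `provenance`).
#'
#' @param path TSV path.
#' @inheritParams term_lexicon
#' @return a [term_lexicon()].
#' @export
read_term_lexicon <- function(path, hierarchy = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = "character", fileEncoding = "UTF-8")
  term_lexicon(df, hierarchy)
}

#' Map verbatim terms to CURIEs through a lexicon
#'
#' Exact lookup of `normalize_term(text)` in the lexicon. Unmapped terms
#' return `NA_character_` — a value, not an error; collect them with
#' [curation_queue()] rather than dropping them.
#'
#' @param text character vector of verbatim terms.
#' @param lexicon a [term_lexicon()].
#' @return character vector of CURIEs, `NA` where unmapped.
#' @examples
#' lx <- term_lexicon(data.frame(verbatim = "curved tail",
#'                               curie = "ZP:0010319"))
#' map_verbatim(c("Curved  Tail.", "zzz"), lx)
#' @export
map_verbatim <- function(text, lexicon) {
  stopifnot(inherits(lexicon, "term_lexicon"))
  unname(lexicon$entries[normalize_term(text)])
}

#' Roll a trait up to its general parent
#'
#' General traits (and the special categories) return themselves; granular
#' traits return their general parent. E.g. a pericardial edema annotation
#' rolls up to abnormal heart.
#'
#' @param curie character vector of trait ids known to the hierarchy.
#' @param hierarchy a [trait_hierarchy()].
#' @return character vector of general trait ids.
#' @export
generalize <- function(curie, hierarchy) {
  stopifnot(inherits(hierarchy, "trait_hierarchy"))
  out <- hierarchy$parent[as.character(curie)]
  if (anyNA(out) & !anyNA(curie)) {
    bad <- unique(curie[is.na(out)])
    stop("unknown trait id(s): ", paste(bad, collapse = ", "))
  }
  out[is.na(curie)] <- NA_character_
  unname(out)
}

#' Harmonize a survey table against a lexicon and hierarchy
#'
#' Every record gains `granular_curie` (the mapped trait, `NA` when the
#' verbatim term is unmapped) and `general_curie` (its roll-up) columns.
#' Survey 1 terms pass through [map_verbatim()]; Survey 2 terms are already
#' trait ids and are only validated against the hierarchy ("dead" is
#' resolved to its CURIE). No rows are lost: the number of annotated
#' records equals the number of input records.
#'
#' @param tab a [survey_table()].
#' @param lexicon a [term_lexicon()].
#' @param hierarchy a [trait_hierarchy()].
#' @return data.frame of class `harmonized_table` with columns `survey`,
#'   `rater`, `specimen`, `verbatim`, `term_norm`, `granular_curie`,
#'   `general_curie`.
#' @export
harmonize_table <- function(tab, lexicon, hierarchy) {
  stopifnot(inherits(tab, "survey_table"),
            inherits(lexicon, "term_lexicon"),
            inherits(hierarchy, "trait_hierarchy"))
  rec <- tab$records
  if (tab$survey_id == "S1") {
    gran <- map_verbatim(rec$term, lexicon)
    verbatim <- rec$term
    term_norm <- normalize_term(rec$term)
  } else {
    term <- rec$term
    dead_id <- if ("dead" %in% names(lexicon$entries))
      lexicon$entries[["dead"]] else "ZP:0000306"
    term[term == "dead"] <- dead_id
    known <- term %in% names(hierarchy$parent)
    if (any(!known)) {
      stop("Survey 2 trait id(s) absent from hierarchy: ",
           paste(unique(term[!known]), collapse = ", "))
    }
    gran <- term
    verbatim <- NA_character_
    term_norm <- term
  }
  gen <- rep(NA_character_, length(gran))
  mapped <- !is.na(gran)
  if (any(mapped)) gen[mapped] <- generalize(gran[mapped], hierarchy)
  out <- data.frame(
    survey = tab$survey_id,
    rater = rec$rater,
    specimen = rec$specimen,
    verbatim = verbatim,
    term_norm = term_norm,
    granular_curie = gran,
    general_curie = gen,
    stringsAsFactors = FALSE)
  class(out) <- c("harmonized_table", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Curation queue of unmapped verbatim terms
#'
#' Unmapped terms are never silently dropped; this collects them (with
#' usage counts) into a table a curator can work through.
#'
#' @param harmonized a [harmonize_table()] result.
#' @return data.frame with columns `term_norm`, `n_records`, `example_verbatim`.
#' @export
curation_queue <- function(harmonized) {
  un <- harmonized[is.na(harmonized$granular_curie), , drop = FALSE]
  if (nrow(un) == 0L) {
    return(data.frame(term_norm = character(), n_records = integer(),
                      example_verbatim = character(),
                      stringsAsFactors = FALSE))
  }
  sp <- split(un, un$term_norm)
  out <- data.frame(
    term_norm = names(sp),
    n_records = vapply(sp, nrow, integer(1)),
    example_verbatim = vapply(sp, function(d) d$verbatim[1L], character(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(-out$n_records, out$term_norm), , drop = FALSE]
}

#' Packaged reference lexicon and hierarchy
#'
#' The lexicon ships the published verbatim-to-CURIE mappings for the
#' abnormal-tail trait family (32 verbatim spellings onto 4 ZP CURIEs) plus
#' curator entries for the whole-specimen categories. The hierarchy holds
#' the full two-level catalog of 21 general and 27 granular traits; ids
#' that were never published get `ZP:UNSPEC_*` placeholders, flagged in the
#' `provenance` column.
#'
#' @return `zp_lexicon()`: a [term_lexicon()]; `zp_hierarchy()`: a
#'   [trait_hierarchy()].
#' @export
zp_hierarchy <- function() {
  read_trait_hierarchy(system.file("extdata", "zp_hierarchy.tsv",
                                   package = "phenoconcord", mustWork = TRUE))
}

#' @rdname zp_hierarchy
#' @export
zp_lexicon <- function() {
  read_term_lexicon(system.file("extdata", "zp_lexicon.tsv",
                                package = "phenoconcord", mustWork = TRUE),
                    hierarchy = zp_hierarchy())
}
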