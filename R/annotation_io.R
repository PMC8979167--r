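#' @keywords internal
"_PACKAGE"

# CURIE syntax: PREFIX:LOCALID, e.g. ZP:0001129. Prefix starts with a letter
# or underscore; local id is alphanumeric (dots/underscores allowed).
curie_pattern <- "^[A-Za-z_][A-Za-z0-9_.]*:[A-Za-z0-9_.]+$"

#' Test whether strings are syntactically valid CURIEs
#'
#' A CURIE (Compact URI) has the form `PREFIX:LOCALID`, e.g. `ZP:0001129`
#' for "abnormal tail" in the Zebrafish Phenotype Ontology.
#'
#' @param x character vector.
#' @return logical vector, `TRUE` where `x` matches the CURIE syntax.
#' @examples
#' is_curie(c("ZP:0001129", "curved tail"))
#' @export
is_curie <- function(x) {
  !is.na(x) & grepl(curie_pattern, x)
}

#' Special (non-CURIE) annotation categories
#'
#' Whole-specimen categories that participate in all downstream statistics
#' but carry no ontology identifier: `normal` and `hatched`. ("dead" has a
#' ZP identifier and is treated as an ordinary trait.)
#'
#' @return character vector of special category names.
#' @export
special_traits <- function() c("normal", "hatched")

# Tokens accepted as Survey 2 terms besides CURIEs: raters could mark a
# specimen normal/hatched/dead; "dead" maps to ZP:0000306 at harmonization.
s2_extra_tokens <- function() c("normal", "hatched", "dead")

#' Construct a validated survey annotation table
#'
#' A `survey_table` holds long-format annotations: one row per
#' (rater, specimen, term) tag. Survey 1 terms are free text; Survey 2 terms
#' are ZP CURIEs (plus the whole-specimen tokens `normal`, `hatched`,
#' `dead`). Blank terms are dropped with a message and exact duplicate
#' (rater, specimen, term) rows are collapsed with a warning.
#'
#' @param records data.frame with character columns `rater`, `specimen`,
#'   `term`.
#' @param survey_id `"S1"` (free text) or `"S2"` (CURIEs).
#' @return object of class `survey_table`: a list with elements `records`
#'   (data.frame), `survey_id`, `raters`, `specimens`.
#' @examples
#' tab <- survey_table(
#'   data.frame(rater = c("A", "B"), specimen = "L01",
#'              term = c("curved tail", "C-tail")),
#'   survey_id = "S1")
#' tab$raters
#' @export
survey_table <- function(records, survey_id = c("S1", "S2")) {
  survey_id <- match.arg(survey_id)
  if (!is.data.frame(records)) stop("`records` must be a data.frame")
  need <- c("rater", "specimen", "term")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  rec <- data.frame(
    rater = as.character(records$rater),
    specimen = as.character(records$specimen),
    term = as.character(records$term),
    stringsAsFactors = FALSE
  )
  blank <- is.na(rec$term) | !nzchar(trimws(rec$term))
  if (any(blank)) {
    message(sum(blank), " record(s) with blank terms dropped")
    rec <- rec[!blank, , drop = FALSE]
  }
  if (nrow(rec) > 0L && (anyNA(rec$rater) || anyNA(rec$specimen))) {
    stop("rater/specimen identifiers must not be missing")
  }
  key <- paste(rec$rater, rec$specimen, rec$term, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    warning(sum(dup), " duplicated (rater, specimen, term) record(s) collapsed")
    rec <- rec[!dup, , drop = FALSE]
  }
  if (survey_id == "S2" && nrow(rec) > 0L) {
    ok <- is_curie(rec$term) | rec$term %in% s2_extra_tokens()
    if (any(!ok)) {
      bad <- which(!ok)
      stop("Survey 2 terms must be CURIEs (PREFIX:LOCALID) or one of ",
           paste(s2_extra_tokens(), collapse = "/"),
           "; offending row(s): ",
           paste(utils::head(bad, 10L), collapse = ", "),
           "; term(s): ",
           paste(utils::head(unique(rec$term[bad]), 5L), collapse = " | "))
    }
  }
  rownames(rec) <- NULL
  structure(
    list(records = rec, survey_id = survey_id,
         raters = sort(unique(rec$rater)),
         specimens = sort(unique(rec$specimen))),
    class = "survey_table")
}

#' @export
print.survey_table <- function(x, ...) {
  cat(sprintf("<survey_table %s: %d records, %d raters, %d specimens>\n",
              x$survey_id, nrow(x$records), length(x$raters),
              length(x$specimens)))
  invisible(x)
}

#' Read a long-format survey annotation file
#'
#' Reads a TSV (default) or CSV file with header columns `rater`,
#' `specimen`, `term` (an optional `survey` column is accepted and ignored).
#' Lines starting with `#` are comments. Files are assumed UTF-8.
#'
#' @param path file path; `.csv` selects comma separation, anything else tab.
#' @param survey_id `"S1"` or `"S2"`; governs term validation (see
#'   [survey_table()]).
#' @param split_cells if `TRUE`, multi-term cells are split on `;` or `,`
#'   (logged). Off by default because free-text endpoint phrases may contain
#'   commas.
#' @return a [survey_table()].
#' @export
read_survey <- function(path, survey_id = c("S1", "S2"), split_cells = FALSE) {
  survey_id <- match.arg(survey_id)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          comment.char = "#", stringsAsFactors = FALSE,
                          check.names = TRUE, colClasses = "character",
                          fileEncoding = "UTF-8")
  need <- c("rater", "specimen", "term")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    stop("schema error in ", path, ": missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (isTRUE(split_cells)) {
    pieces <- strsplit(df$term, "[;,]")
    n_each <- lengths(pieces)
    if (any(n_each > 1L)) {
      message(sum(n_each > 1L), " multi-term cell(s) split on ;/,")
    }
    df <- data.frame(
      rater = rep(df$rater, n_each),
      specimen = rep(df$specimen, n_each),
      term = trimws(unlist(pieces)),
      stringsAsFactors = FALSE)
  }
  survey_table(df, survey_id)
}

#' Write a survey table to TSV/CSV
#'
#' Inverse of [read_survey()]: writes columns
#' `survey`, `rater`, `specimen`, `term`.
#'
#' @param tab a [survey_table()].
#' @param path output path; `.csv` selects comma separation, else tab.
#' @return `path`, invisibly.
#' @export
write_survey <- function(tab, path) {
  stopifnot(inherits(tab, "survey_table"))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  out <- cbind(survey = tab$survey_id, tab$records)
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Raters who took both surveys
#'
#' The analysis is restricted to participants present in both surveys;
#' this returns the intersection of the two rater sets and errors if it is
#' empty (no analyzable raters).
#'
#' @param s1,s2 [survey_table()] objects.
#' @return character vector of rater ids.
#' @export
paired_raters <- function(s1, s2) {
  stopifnot(inherits(s1, "survey_table"), inherits(s2, "survey_table"))
  both <- intersect(s1$raters, s2$raters)
  if (length(both) == 0L) {
    stop("no raters took both surveys: nothing to analyze")
  }
  sort(both)
}

#' Restrict a survey table to a set of raters
#'
#' @param tab a [survey_table()].
#' @param raters character vector of rater ids to keep.
#' @return a [survey_table()] containing only those raters' records.
#' @export
restrict_raters <- function(tab, raters) {
  stopifnot(inherits(tab, "survey_table"))
  rec <- tab$records[tab$records$rater %in% raters, , drop = FALSE]
  if (nrow(rec) == 0L) stop("no records left after rater restriction")
  suppressMessages(survey_table(rec, tab$survey_id))
}
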