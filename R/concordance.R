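#' Binary rater x specimen x trait presence array
#'
#' Builds the 0/1 tensor "rater r tagged trait t on specimen s" from a
#' harmonized table, at the general or granular trait level. Absent
#' (rater, specimen, trait) combinations are 0. Axis sets default to the
#' values observed in the table but can be fixed (e.g. to align the two
#' surveys on common axes).
#'
#' @param harmonized a [harmonize_table()] result (unmapped records are
#'   ignored).
#' @param level `"general"` or `"granular"`.
#' @param raters,specimens,traits optional axis values; defaults to sorted
#'   observed values.
#' @return 3-d integer array with dimnames `rater`, `specimen`, `trait` and
#'   attributes `level` and `survey`.
#' @export
presence_matrix <- function(harmonized, level = c("general", "granular"),
                            raters = NULL, specimens = NULL, traits = NULL) {
  level <- match.arg(level)
  h <- harmonized[!is.na(harmonized$granular_curie), , drop = FALSE]
  if (nrow(h) == 0L) stop("no mapped records: cannot build presence matrix")
  tr <- if (level == "general") h$general_curie else h$granular_curie
  raters <- if (is.null(raters)) sort(unique(h$rater)) else as.character(raters)
  specimens <- if (is.null(specimens)) sort(unique(h$specimen)) else
    as.character(specimens)
  traits <- if (is.null(traits)) sort(unique(tr)) else as.character(traits)
  m <- array(0L, dim = c(length(raters), length(specimens), length(traits)),
             dimnames = list(rater = raters, specimen = specimens,
                             trait = traits))
  keep <- h$rater %in% raters & h$specimen %in% specimens & tr %in% traits
  h <- h[keep, , drop = FALSE]
  tr <- tr[keep]
  m[cbind(match(h$rater, raters), match(h$specimen, specimens),
          match(tr, traits))] <- 1L
  attr(m, "level") <- level
  attr(m, "survey") <- unique(harmonized$survey)[1L]
  m
}

#' Observed (specimen, trait) universe across surveys
#'
#' The columns over which concordance is scored: (specimen, trait) pairs
#' tagged by at least one rater in at least one of the supplied presence
#' matrices. Scoring all catalog traits everywhere would inflate
#' concordance through universal mutual absence.
#'
#' @param ... presence matrices from [presence_matrix()] sharing specimen
#'   and trait axes.
#' @return data.frame with columns `specimen`, `trait`.
#' @export
observed_universe <- function(...) {
  mats <- list(...)
  stopifnot(length(mats) >= 1L)
  tagged <- Reduce(`+`, lapply(mats, function(m) apply(m, c(2, 3), sum)))
  idx <- which(tagged >= 1, arr.ind = TRUE)
  out <- data.frame(specimen = rownames(tagged)[idx[, 1L]],
                    trait = colnames(tagged)[idx[, 2L]],
                    stringsAsFactors = FALSE)
  out[order(out$specimen, out$trait), , drop = FALSE]
}

#' Majority call for one (specimen, trait) column
#'
#' 1 iff strictly more than half of the raters tagged the trait on the
#' specimen. An exact tie (possible with an even rater count) resolves to 0
#' (trait called absent) — a conservative, deterministic policy.
#'
#' @param m a [presence_matrix()].
#' @param specimen,trait axis values.
#' @return 0 or 1.
#' @export
majority_call <- function(m, specimen, trait) {
  n <- dim(m)[1L]
  if (n < 2L) stop("majority requires at least 2 raters")
  k <- sum(m[, specimen, trait])
  as.integer(k > n / 2)
}

#' Per-rater concordance with the majority
#'
#' For every rater and every (specimen, trait) column in the universe,
#' `concordant` is 1 iff the rater's binary presence equals the majority
#' call. Ties are resolved per the policy of [majority_call()] by default;
#' `tie = "drop"` removes tied columns instead. The number of tied columns
#' is reported with a message.
#'
#' @param m a [presence_matrix()] (>= 2 raters).
#' @param universe optional data.frame (`specimen`, `trait`) restricting
#'   scored columns, e.g. from [observed_universe()] over both surveys;
#'   default: columns tagged at least once in `m` itself.
#' @param tie `"absent"` (tie -> majority 0) or `"drop"`.
#' @return data.frame of class `concordance_cells` with columns `rater`,
#'   `specimen`, `trait`, `presence`, `majority`, `concordant`; attributes
#'   `survey`, `level`, `n_ties`.
#' @export
concordance_cells <- function(m, universe = NULL,
                              tie = c("absent", "drop")) {
  tie <- match.arg(tie)
  n <- dim(m)[1L]
  if (n < 2L) stop("concordance requires at least 2 raters")
  if (is.null(universe)) universe <- observed_universe(m)
  stopifnot(all(c("specimen", "trait") %in% names(universe)))
  si <- match(universe$specimen, dimnames(m)$specimen)
  ti <- match(universe$trait, dimnames(m)$trait)
  if (anyNA(si) || anyNA(ti)) {
    stop("universe contains specimen/trait values absent from the matrix")
  }
  counts <- apply(m, c(2, 3), sum)
  k <- counts[cbind(si, ti)]
  tied <- k * 2L == n
  if (any(tied)) {
    message(sum(tied), " tied (specimen, trait) column(s): ",
            if (tie == "drop") "dropped" else "majority resolved to absent")
    if (tie == "drop") {
      universe <- universe[!tied, , drop = FALSE]
      si <- si[!tied]; ti <- ti[!tied]; k <- k[!tied]
    }
  }
  maj <- as.integer(k > n / 2)
  nr <- nrow(universe)
  raters <- dimnames(m)$rater
  pres <- m[cbind(rep(seq_len(n), times = nr),
                  rep(si, each = n),
                  rep(ti, each = n))]
  out <- data.frame(
    rater = rep(raters, times = nr),
    specimen = rep(universe$specimen, each = n),
    trait = rep(universe$trait, each = n),
    presence = pres,
    majority = rep(maj, each = n),
    concordant = as.integer(pres == rep(maj, each = n)),
    stringsAsFactors = FALSE)
  class(out) <- c("concordance_cells", "data.frame")
  attr(out, "survey") <- attr(m, "survey")
  attr(out, "level") <- attr(m, "level")
  attr(out, "n_ties") <- sum(tied)
  out
}

#' Mean concordance by rater, specimen, or trait
#'
#' Per-group mean of the binary concordance cells, with the across-group
#' standard deviation of the group means (the scale on which survey-level
#' "mean +/- sd" figures are quoted) and the pooled mean attached as
#' attributes.
#'
#' @param cells a [concordance_cells()] result.
#' @param group_by `"rater"`, `"specimen"` or `"trait"`.
#' @return data.frame with columns `group`, `n_cells`, `mean_concordance`;
#'   attributes `pooled_mean`, `between_group_sd`, `group_by`.
#' @export
mean_concordance <- function(cells, group_by = c("rater", "specimen",
                                                 "trait")) {
  group_by <- match.arg(group_by)
  if (nrow(cells) == 0L) stop("no concordance cells")
  g <- cells[[group_by]]
  sp <- split(cells$concordant, g)
  out <- data.frame(
    group = names(sp),
    n_cells = vapply(sp, length, integer(1)),
    mean_concordance = vapply(sp, mean, numeric(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "pooled_mean") <- mean(cells$concordant)
  attr(out, "between_group_sd") <- stats::sd(out$mean_concordance)
  attr(out, "group_by") <- group_by
  out
}

#' Between-survey change in concordance with exact tests
#'
#' For each unit (rater x trait, rater, or trait), counts concordant and
#' discordant cells in each survey, their difference
#' `delta = n_concordant_s2 - n_concordant_s1`, and a two-sided Fisher
#' exact p-value on the 2x2 table
#' `[[concordant_s1, discordant_s1], [concordant_s2, discordant_s2]]`.
#' Raw p-values are reported with a Benjamini-Hochberg adjusted column.
#'
#' @param cells_s1,cells_s2 [concordance_cells()] for the two surveys,
#'   built over the same raters, specimens, and traits.
#' @param unit `"rater_trait"`, `"rater"` or `"trait"`.
#' @return data.frame with columns `unit`, (`rater`/`trait` as relevant),
#'   `n_concordant_s1`, `n_total_s1`, `mean_s1`, `n_concordant_s2`,
#'   `n_total_s2`, `mean_s2`, `delta`, `p_value`, `q_bh`.
#' @export
concordance_change <- function(cells_s1, cells_s2,
                               unit = c("rater_trait", "rater", "trait")) {
  unit <- match.arg(unit)
  for (ax in c("rater", "specimen", "trait")) {
    if (!setequal(unique(cells_s1[[ax]]), unique(cells_s2[[ax]]))) {
      stop("surveys disagree on the ", ax, " axis")
    }
  }
  key_of <- function(cells) switch(unit,
    rater_trait = paste(cells$rater, cells$trait, sep = "\r"),
    rater = cells$rater,
    trait = cells$trait)
  k1 <- key_of(cells_s1); k2 <- key_of(cells_s2)
  keys <- sort(union(unique(k1), unique(k2)))
  rows <- lapply(keys, function(k) {
    c1 <- cells_s1$concordant[k1 == k]
    c2 <- cells_s2$concordant[k2 == k]
    tab <- matrix(c(sum(c1), length(c1) - sum(c1),
                    sum(c2), length(c2) - sum(c2)),
                  nrow = 2, byrow = TRUE)
    data.frame(
      unit = gsub("\r", ":", k),
      rater = if (unit != "trait") strsplit(k, "\r")[[1L]][1L] else
        NA_character_,
      trait = switch(unit, rater_trait = strsplit(k, "\r")[[1L]][2L],
                     trait = k, rater = NA_character_),
      n_concordant_s1 = tab[1, 1], n_total_s1 = sum(tab[1, ]),
      mean_s1 = tab[1, 1] / sum(tab[1, ]),
      n_concordant_s2 = tab[2, 1], n_total_s2 = sum(tab[2, ]),
      mean_s2 = tab[2, 1] / sum(tab[2, ]),
      delta = tab[2, 1] - tab[1, 1],
      p_value = fisher_exact_2x2(tab),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_bh <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Conditional on the margins, the two-sided p-value is the sum of
#' hypergeometric probabilities of all tables whose probability does not
#' exceed that of the observed table (with the customary 1 + 1e-7 relative
#' slack against floating-point ties). A zero margin admits only one table,
#' so p = 1 by convention.
#'
#' @param tab 2x2 matrix (or coercible) of non-negative integer counts.
#' @return two-sided p-value in (0, 1].
#' @examples
#' fisher_exact_2x2(matrix(c(10, 0, 0, 10), 2, byrow = TRUE))
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("need a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab)) || anyNA(tab)) {
    stop("counts must be non-negative integers")
  }
  a <- tab[1, 1]
  m1 <- sum(tab[1, ]); m2 <- sum(tab[2, ])
  k <- sum(tab[, 1]); l <- sum(tab[, 2])
  if (m1 == 0 || m2 == 0 || k == 0 || l == 0) return(1)
  N <- m1 + m2
  x <- max(0, k - m2):min(k, m1)
  logp <- lchoose(m1, x) + lchoose(m2, k - x) - lchoose(N, k)
  p <- exp(logp)
  p_obs <- p[x == a]
  min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
}

#' Pearson product-moment correlation
#'
#' Standard Pearson r with the preconditions this analysis needs made
#' explicit: equal lengths of at least 3 and nonzero variance in both
#' vectors. Used to relate per-trait mean concordance to unique-term
#' counts and to the number of specimens showing the trait.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return correlation in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: zero variance")
  }
  stats::cor(x, y)
}
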