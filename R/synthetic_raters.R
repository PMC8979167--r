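# Deterministic synonym generation for a trait label: the label itself plus
# phrase variants and an initials abbreviation, mimicking how laboratories
# shorten endpoint names ("abnormally curved tail" -> "curved tail", "ACT").
make_synonyms <- function(label, n) {
  core <- sub("^abnormally? ", "", label)
  initials <- toupper(paste(substr(strsplit(core, "[ -]")[[1L]], 1L, 1L),
                            collapse = ""))
  cands <- unique(c(label, core, paste(core, "malformation"),
                    initials, paste("possible", label),
                    paste("slight", core), paste(core, "defect"),
                    paste(label, "observed")))
  cands[seq_len(min(n, length(cands)))]
}

#' Default simulated trait catalog
#'
#' Builds the simulator's trait catalog from the packaged two-level
#' hierarchy ([zp_hierarchy()]): one "unit" per granular trait (childless
#' general traits are their own unit), per-general prevalence taken as
#' (number of specimens showing the trait) / 24 from the packaged count
#' table ([survey1_trait_counts()]), and per-trait synonym lists with
#' geometric-style categorical weights. Synonym strings are globally
#' disjoint after normalization, so the emitted lexicon is conflict-free
#' and covers every generated verbatim term by construction.
#'
#' @param n_synonyms synonyms per trait (>= 1, <= 8).
#' @return object of class `trait_catalog`: list with `units` (data.frame
#'   `unit`, `general`, `prevalence`), `generals`, `synonyms` (named list),
#'   `weights` (named list), `labels`, `hierarchy_df`.
#' @export
default_trait_catalog <- function(n_synonyms = 4L) {
  stopifnot(n_synonyms >= 1L, n_synonyms <= 8L)
  h <- zp_hierarchy()
  counts <- survey1_trait_counts()
  prev <- stats::setNames(counts$n_specimens / 24, counts$curie)
  generals <- h$generals
  prevalence <- unname(prev[generals])
  # generals the count table does not cover (placeholder ids) get a low
  # default prevalence
  prevalence[is.na(prevalence)] <- 2 / 24
  names(prevalence) <- generals
  unit_rows <- lapply(generals, function(g) {
    kids <- h$granulars[h$parent[h$granulars] == g]
    units <- if (length(kids) > 0L) kids else g
    data.frame(unit = units, general = g,
               prevalence = unname(prevalence[g]),
               stringsAsFactors = FALSE)
  })
  units <- do.call(rbind, unit_rows)
  trait_ids <- unique(c(generals, h$granulars, "normal"))
  labels <- c(h$labels, normal = "normal")
  synonyms <- list()
  used <- character()
  for (tr in trait_ids) {
    syn <- make_synonyms(unname(labels[tr]), n_synonyms)
    keep <- !(normalize_term(syn) %in% used)
    syn <- syn[keep]
    if (length(syn) == 0L) syn <- paste(unname(labels[tr]), "variant")
    used <- c(used, normalize_term(syn))
    synonyms[[tr]] <- syn
  }
  weights <- lapply(synonyms, function(s) {
    w <- 2^-(seq_along(s) - 1L)
    w / sum(w)
  })
  structure(
    list(units = units, generals = generals, synonyms = synonyms,
         weights = weights, labels = labels,
         hierarchy_df = h$table[h$table$granular_curie != "hatched", ,
                                drop = FALSE]),
    class = "trait_catalog")
}

#' Simulation configuration for multi-rater annotation surveys
#'
#' Defines the generative model: per-specimen true trait sets drawn from
#' per-trait prevalences with a specimen random effect; per-rater detection
#' with sensitivity (logit-shifted by a rater random effect) and
#' per-trait specificity; free-text reporting through per-rater synonym
#' idiolects with a general-vs-granular reporting preference; and
#' controlled-vocabulary reporting with a small term-choice error. The
#' defaults mirror the survey design under study: 18 raters, 24 specimens,
#' prevalences from the published per-trait specimen counts.
#'
#' @param n_raters number of raters (default 18).
#' @param n_specimens number of specimens/larvae (default 24).
#' @param catalog a [default_trait_catalog()].
#' @param sensitivity probability a rater detects a truly present trait
#'   (before the rater effect; default 0.85). A scalar, or a vector of
#'   length `n_raters` for rater-specific baselines.
#' @param specificity per-trait probability of not falsely tagging an
#'   absent trait (default 0.97).
#' @param p_general probability a detected granular trait is reported with
#'   the general term in the free-text survey (default 0.35).
#' @param rater_effect_sd SD of the rater effect on the logit of
#'   sensitivity (default 0.5).
#' @param specimen_effect_sd SD of the specimen effect on the logit of
#'   prevalence (default 0.8).
#' @param choice_error probability the controlled-vocabulary survey
#'   substitutes the general CURIE for a granular one (default 0.05).
#' @param idiolect_size synonyms per trait in one rater's personal
#'   vocabulary (default 2).
#' @param seed integer seed; fully determines [generate()] output.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_raters = 18L, n_specimens = 24L,
                       catalog = default_trait_catalog(),
                       sensitivity = 0.85, specificity = 0.97,
                       p_general = 0.35, rater_effect_sd = 0.5,
                       specimen_effect_sd = 0.8, choice_error = 0.05,
                       idiolect_size = 2L, seed = 1L) {
  if (!length(sensitivity) %in% c(1L, n_raters)) {
    stop("sensitivity must be a scalar or one value per rater")
  }
  probs <- c(sensitivity, specificity = specificity,
             p_general = p_general, choice_error = choice_error)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]")
  }
  if (any(catalog$units$prevalence < 0 | catalog$units$prevalence > 1)) {
    stop("catalog prevalences must lie in [0, 1]")
  }
  if (rater_effect_sd < 0 || specimen_effect_sd < 0) {
    stop("random-effect SDs must be >= 0")
  }
  if (n_raters < 2L) stop("need at least 2 raters")
  if (n_specimens < 1L) stop("need at least 1 specimen")
  if (idiolect_size < 1L) stop("idiolect_size must be >= 1")
  structure(
    list(n_raters = as.integer(n_raters),
         n_specimens = as.integer(n_specimens), catalog = catalog,
         sensitivity = sensitivity, specificity = specificity,
         p_general = p_general, rater_effect_sd = rater_effect_sd,
         specimen_effect_sd = specimen_effect_sd,
         choice_error = choice_error,
         idiolect_size = as.integer(idiolect_size),
         seed = as.integer(seed)),
    class = "sim_config")
}

#' Generate synthetic paired annotation surveys
#'
#' Samples ground truth and both surveys from a [sim_config()]. Truth:
#' each specimen shows each general trait with probability
#' `plogis(qlogis(prevalence) + specimen_effect)`; a shown general trait
#' manifests as one uniformly chosen granular unit. Detection: each survey
#' is an independent viewing session in which each rater
#' detects each true unit with probability
#' `plogis(qlogis(sensitivity) + rater_effect)` and falsely tags each
#' absent unit with probability `1 - specificity`. Reporting: the
#' free-text survey renders a detected unit as a synonym drawn from the
#' rater's idiolect (of the general trait with probability `p_general`);
#' the controlled survey reports the unit's CURIE, substituting the
#' general CURIE with probability `choice_error`. A rater who detects
#' nothing on a specimen tags it `normal`. The emitted lexicon covers
#' every generated verbatim string by construction.
#'
#' @param config a [sim_config()].
#' @return object of class `sim_output`: list with `truth_general`
#'   (specimen x general 0/1 matrix), `truth_unit` (specimen x unit),
#'   `survey1`, `survey2` ([survey_table()]s), `lexicon`, `hierarchy`,
#'   `effects` (rater/specimen random effects), `config`.
#' @export
generate <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  catal <- config$catalog
  nR <- config$n_raters
  nS <- config$n_specimens
  raters <- sprintf("R%02d", seq_len(nR))
  specimens <- sprintf("L%02d", seq_len(nS))
  units <- catal$units$unit
  unit_general <- stats::setNames(catal$units$general, units)
  nU <- length(units)
  generals <- catal$generals

  b_s <- stats::rnorm(nS, 0, config$specimen_effect_sd)
  a_r <- stats::rnorm(nR, 0, config$rater_effect_sd)

  # ground truth: general traits per specimen, then one unit per hit
  prev_g <- stats::setNames(
    catal$units$prevalence[!duplicated(catal$units$general)],
    catal$units$general[!duplicated(catal$units$general)])
  truth_general <- matrix(0L, nS, length(generals),
                          dimnames = list(specimen = specimens,
                                          general = generals))
  truth_unit <- matrix(0L, nS, nU,
                       dimnames = list(specimen = specimens, unit = units))
  for (s in seq_len(nS)) {
    p <- stats::plogis(stats::qlogis(prev_g[generals]) + b_s[s])
    hit <- stats::runif(length(generals)) < p
    truth_general[s, ] <- as.integer(hit)
    for (g in generals[hit]) {
      cand <- units[unit_general == g]
      u <- if (length(cand) == 1L) cand else sample(cand, 1L)
      truth_unit[s, u] <- 1L
    }
  }

  # per-rater idiolects: a favorite synonym subset per trait
  trait_ids <- names(catal$synonyms)
  idiolect <- lapply(seq_len(nR), function(r) {
    stats::setNames(lapply(trait_ids, function(tr) {
      syn <- catal$synonyms[[tr]]
      k <- min(config$idiolect_size, length(syn))
      if (length(syn) == 1L) syn else
        sample(syn, k, prob = catal$weights[[tr]])
    }), trait_ids)
  })

  sens_base <- rep(config$sensitivity, length.out = nR)
  sens_r <- stats::plogis(stats::qlogis(sens_base) + a_r)
  fp <- 1 - config$specificity

  # each survey is a separate viewing session: detection is drawn
  # independently per survey from the same truth, rater, and specimen state
  detect <- function(r, s) {
    tru <- truth_unit[s, ] == 1L
    det <- logical(nU)
    det[tru] <- stats::runif(sum(tru)) < sens_r[r]
    det[!tru] <- stats::runif(sum(!tru)) < fp
    units[det]
  }
  rows1 <- list(); rows2 <- list()
  for (r in seq_len(nR)) {
    for (s in seq_len(nS)) {
      du <- detect(r, s)
      if (length(du) == 0L) {
        syn <- idiolect[[r]][["normal"]]
        t1 <- if (length(syn) == 1L) syn else sample(syn, 1L)
        rows1[[length(rows1) + 1L]] <- c(raters[r], specimens[s], t1)
      } else {
        for (u in du) {
          g <- unit_general[[u]]
          rep_gen <- u != g && stats::runif(1) < config$p_general
          tr1 <- if (rep_gen) g else u
          syn <- idiolect[[r]][[tr1]]
          t1 <- if (length(syn) == 1L) syn else sample(syn, 1L)
          rows1[[length(rows1) + 1L]] <- c(raters[r], specimens[s], t1)
        }
      }
      du <- detect(r, s)
      if (length(du) == 0L) {
        rows2[[length(rows2) + 1L]] <- c(raters[r], specimens[s], "normal")
      } else {
        for (u in du) {
          g <- unit_general[[u]]
          err <- u != g && stats::runif(1) < config$choice_error
          t2 <- if (err) g else u
          rows2[[length(rows2) + 1L]] <- c(raters[r], specimens[s], t2)
        }
      }
    }
  }
  as_df <- function(rows) {
    m <- do.call(rbind, rows)
    unique(data.frame(rater = m[, 1L], specimen = m[, 2L], term = m[, 3L],
                      stringsAsFactors = FALSE))
  }
  survey1 <- suppressMessages(survey_table(as_df(rows1), "S1"))
  survey2 <- suppressMessages(survey_table(as_df(rows2), "S2"))

  lex_df <- do.call(rbind, lapply(trait_ids, function(tr) {
    data.frame(verbatim = catal$synonyms[[tr]], curie = tr,
               provenance = "simulator", stringsAsFactors = FALSE)
  }))
  hier_df <- catal$hierarchy_df
  if (!"normal" %in% hier_df$granular_curie) {
    hier_df <- rbind(hier_df[, c("granular_curie", "general_curie", "label")],
                     data.frame(granular_curie = "normal",
                                general_curie = "normal", label = "normal",
                                stringsAsFactors = FALSE))
  }
  hierarchy <- trait_hierarchy(hier_df)
  lexicon <- term_lexicon(lex_df, hierarchy)

  structure(
    list(truth_general = truth_general, truth_unit = truth_unit,
         survey1 = survey1, survey2 = survey2,
         lexicon = lexicon, hierarchy = hierarchy,
         effects = list(rater = stats::setNames(a_r, raters),
                        specimen = stats::setNames(b_s, specimens)),
         config = config),
    class = "sim_output")
}

#' @export
print.sim_output <- function(x, ...) {
  cat(sprintf(
    "<sim_output: %d raters x %d specimens; %d + %d survey records>\n",
    x$config$n_raters, x$config$n_specimens,
    nrow(x$survey1$records), nrow(x$survey2$records)))
  invisible(x)
}

#' Parameter-recovery diagnostics for a simulated survey pair
#'
#' Compares realized against configured/expected values: per-general-trait
#' prevalence (from the truth matrix, against the configured prevalence at
#' the binomial tolerance), per-rater detection sensitivity (from the
#' controlled survey's presence of truly present general traits, against
#' the rater's logit-shifted sensitivity), per-rater false-tag rate, and
#' per-trait unique-term counts against the synonym pool size.
#'
#' @param sim a [generate()] result.
#' @param z half-width multiplier on the binomial standard error used for
#'   the pass/fail tolerance (default 3).
#' @param floor_tol minimum tolerance (default 0.02).
#' @return data.frame with columns `check`, `id`, `expected`, `observed`,
#'   `tol`, `pass`.
#' @export
recover_parameters <- function(sim, z = 3, floor_tol = 0.02) {
  stopifnot(inherits(sim, "sim_output"))
  cfg <- sim$config
  h2 <- harmonize_table(sim$survey2, sim$lexicon, sim$hierarchy)
  m2g <- presence_matrix(h2, level = "general",
                         raters = sort(sim$survey2$raters),
                         specimens = rownames(sim$truth_general),
                         traits = colnames(sim$truth_general))
  nS <- cfg$n_specimens
  prev_g <- stats::setNames(
    cfg$catalog$units$prevalence[!duplicated(cfg$catalog$units$general)],
    cfg$catalog$units$general[!duplicated(cfg$catalog$units$general)])
  rows <- list()
  for (g in colnames(sim$truth_general)) {
    p <- unname(prev_g[g])
    tol <- max(floor_tol, z * sqrt(p * (1 - p) / nS))
    obs <- mean(sim$truth_general[, g])
    rows[[length(rows) + 1L]] <- data.frame(
      check = "prevalence", id = g, expected = p, observed = obs,
      tol = tol, pass = abs(obs - p) <= tol, stringsAsFactors = FALSE)
  }
  sens_r <- stats::plogis(
    stats::qlogis(rep(cfg$sensitivity, length.out = cfg$n_raters)) +
      sim$effects$rater)
  for (r in names(sens_r)) {
    true_cells <- which(sim$truth_general == 1L, arr.ind = TRUE)
    pres <- m2g[cbind(match(r, dimnames(m2g)$rater), true_cells[, 1L],
                      true_cells[, 2L])]
    n_true <- nrow(true_cells)
    exp_det <- unname(sens_r[r])
    tol <- max(floor_tol, z * sqrt(exp_det * (1 - exp_det) / n_true)) + 0.05
    obs <- mean(pres)
    rows[[length(rows) + 1L]] <- data.frame(
      check = "sensitivity", id = r, expected = exp_det, observed = obs,
      tol = tol, pass = abs(obs - exp_det) <= tol, stringsAsFactors = FALSE)
  }
  # false tags at unit level, restricted to units whose general is truly
  # absent so choice-error promotion cannot contaminate the cell
  m2u <- presence_matrix(h2, level = "granular",
                         raters = sort(sim$survey2$raters),
                         specimens = rownames(sim$truth_unit),
                         traits = colnames(sim$truth_unit))
  unit_general <- stats::setNames(cfg$catalog$units$general,
                                  cfg$catalog$units$unit)
  exp_fp <- (1 - cfg$specificity) * (1 - cfg$choice_error)
  for (r in dimnames(m2u)$rater) {
    gen_absent <- sim$truth_general[, unit_general[colnames(sim$truth_unit)],
                                    drop = FALSE] == 0L
    cells <- which(gen_absent, arr.ind = TRUE)
    pres <- m2u[cbind(match(r, dimnames(m2u)$rater), cells[, 1L],
                      cells[, 2L])]
    tol <- max(floor_tol, z * sqrt(exp_fp * (1 - exp_fp) / nrow(cells)))
    obs <- mean(pres)
    rows[[length(rows) + 1L]] <- data.frame(
      check = "false_tag_rate", id = r, expected = exp_fp, observed = obs,
      tol = tol, pass = abs(obs - exp_fp) <= tol, stringsAsFactors = FALSE)
  }
  h1 <- harmonize_table(sim$survey1, sim$lexicon, sim$hierarchy)
  for (tr in unique(h1$granular_curie)) {
    pool <- length(cfg$catalog$synonyms[[tr]])
    obs <- length(unique(h1$term_norm[h1$granular_curie == tr]))
    rows[[length(rows) + 1L]] <- data.frame(
      check = "unique_terms_within_pool", id = tr, expected = pool,
      observed = obs, tol = 0, pass = obs <= pool, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
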