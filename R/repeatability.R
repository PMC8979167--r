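#' One-way variance-components intraclass correlation (repeatability)
#'
#' ANOVA estimator of ICC(1) for observations grouped by a single factor
#' (specimen, trait, or rater): with `g` groups of sizes `n_i`, total `N`,
#' between/within mean squares `MSB`/`MSW` and effective group size
#' `k0 = (N - sum(n_i^2)/N) / (g - 1)`,
#' `var_between = max(0, (MSB - MSW)/k0)`, `var_within = MSW`, and
#' `icc = var_between / (var_between + var_within)`. Negative
#' between-group variance estimates are truncated to 0, so the ICC lies in
#' \[0, 1\]. Applied here on the original 0/1 scale of concordance or
#' presence observations.
#'
#' @param values numeric (typically binary) observations.
#' @param groups grouping labels, same length as `values`.
#' @return object of class `icc_estimate`: list with `icc`, `var_between`,
#'   `var_within`, `n_groups`, `n_obs`, `ms_between`, `ms_within`, `k0`.
#' @examples
#' icc_anova(c(0, 0, 1, 1), c("a", "a", "b", "b"))$icc  # 1
#' @export
icc_anova <- function(values, groups) {
  if (length(values) != length(groups)) {
    stop("values and groups must have equal length")
  }
  keep <- !is.na(values) & !is.na(groups)
  values <- as.numeric(values[keep])
  groups <- as.character(groups[keep])
  n_i <- table(groups)
  g <- length(n_i)
  N <- length(values)
  if (g < 2L) stop("need at least 2 groups")
  if (N <= g) stop("need at least one group with >= 2 observations")
  est <- function(icc, vb, vw, msb = NA_real_, msw = NA_real_,
                  k0 = NA_real_) {
    structure(list(icc = icc, var_between = vb, var_within = vw,
                   n_groups = g, n_obs = N, ms_between = msb,
                   ms_within = msw, k0 = k0),
              class = "icc_estimate")
  }
  if (stats::var(values) == 0) {
    warning("constant data: ICC set to 0")
    return(est(0, 0, 0))
  }
  gm <- mean(values)
  means <- vapply(split(values, groups), mean, numeric(1))
  n_vec <- as.numeric(n_i[names(means)])
  ssb <- sum(n_vec * (means - gm)^2)
  ssw <- sum((values - means[groups])^2)
  msb <- ssb / (g - 1)
  msw <- ssw / (N - g)
  k0 <- (N - sum(n_vec^2) / N) / (g - 1)
  vb <- max(0, (msb - msw) / k0)
  vw <- msw
  icc <- if (vb + vw == 0) 0 else vb / (vb + vw)
  est(icc, vb, vw, msb, msw, k0)
}

#' @export
print.icc_estimate <- function(x, ...) {
  cat(sprintf(
    "<icc_estimate: icc = %.3f (var_between %.4f, var_within %.4f; %d groups, %d obs)>\n",
    x$icc, x$var_between, x$var_within, x$n_groups, x$n_obs))
  invisible(x)
}

#' Bootstrap percentile confidence interval for the ICC
#'
#' Resamples whole groups with replacement, recomputes [icc_anova()] on
#' each replicate, and returns the percentile 95% interval. Constant
#' resamples (possible when whole groups are constant) carry no information
#' about the variance ratio and are excluded. Seeded and fully
#' reproducible.
#'
#' @param values,groups as in [icc_anova()].
#' @param B number of bootstrap replicates (>= 100).
#' @param seed integer RNG seed.
#' @param level confidence level (default 0.95).
#' @return named numeric `c(ci_low, ci_high)`.
#' @export
icc_bootstrap_ci <- function(values, groups, B = 1000L, seed = 1L,
                             level = 0.95) {
  if (B < 100L) stop("B must be >= 100")
  keep <- !is.na(values) & !is.na(groups)
  values <- as.numeric(values[keep])
  groups <- as.character(groups[keep])
  by_group <- split(values, groups)
  g <- length(by_group)
  if (g < 2L) stop("need at least 2 groups")
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  reps <- vapply(seq_len(B), function(b) {
    pick <- sample.int(g, g, replace = TRUE)
    vals <- unlist(by_group[pick], use.names = FALSE)
    grps <- rep(seq_len(g), lengths(by_group)[pick])
    # a constant resample carries no information about the variance ratio
    if (stats::var(vals) == 0) return(NA_real_)
    tryCatch(icc_anova(vals, grps)$icc, error = function(e) NA_real_)
  }, numeric(1))
  reps <- reps[!is.na(reps)]
  if (length(reps) == 0L) {
    obs <- suppressWarnings(icc_anova(values, groups)$icc)
    return(c(ci_low = obs, ci_high = obs))
  }
  alpha <- (1 - level) / 2
  ci <- stats::quantile(reps, c(alpha, 1 - alpha), names = FALSE, type = 7)
  c(ci_low = ci[1L], ci_high = ci[2L])
}

#' Repeatability table across factors, surveys, and trait levels
#'
#' Computes [icc_anova()] for every combination of grouping factor
#' (specimen, trait, rater), survey, and annotation granularity present in
#' the input — the standard 2 granularities x 3 factors x 2 surveys layout
#' gives 12 rows. Optionally adds bootstrap percentile CIs.
#'
#' @param cells data.frame with columns `survey`, `level`, `rater`,
#'   `specimen`, `trait`, and a response column (default `concordant`;
#'   `response = "presence"` scores raw presence instead).
#' @param response name of the 0/1 response column.
#' @param B bootstrap replicates for CIs; `0` (default) skips CIs.
#' @param seed RNG seed for the bootstrap.
#' @return data.frame with columns `granularity`, `factor`, `survey`,
#'   `icc`, `ci_low`, `ci_high`, `var_between`, `var_within`, `n_groups`,
#'   `n_obs`.
#' @export
icc_table <- function(cells, response = "concordant", B = 0L, seed = 1L) {
  need <- c("survey", "level", "rater", "specimen", "trait", response)
  missing_cols <- setdiff(need, names(cells))
  if (length(missing_cols) > 0L) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  combos <- expand.grid(
    granularity = sort(unique(cells$level)),
    factor = c("specimen", "trait", "rater"),
    survey = sort(unique(cells$survey)),
    stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    cm <- combos[i, ]
    d <- cells[cells$survey == cm$survey & cells$level == cm$granularity, ]
    fit <- suppressWarnings(icc_anova(d[[response]], d[[cm$factor]]))
    ci <- if (B >= 100L) {
      icc_bootstrap_ci(d[[response]], d[[cm$factor]], B = B,
                       seed = seed + i)
    } else c(ci_low = NA_real_, ci_high = NA_real_)
    data.frame(granularity = cm$granularity, factor = cm$factor,
               survey = cm$survey, icc = fit$icc,
               ci_low = ci[["ci_low"]], ci_high = ci[["ci_high"]],
               var_between = fit$var_between, var_within = fit$var_within,
               n_groups = fit$n_groups, n_obs = fit$n_obs,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
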