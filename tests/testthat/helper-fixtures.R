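# Small in-code fixtures shared across test files.

# a tiny two-level hierarchy: tail family + a childless trait + specials
toy_hierarchy <- function() {
  trait_hierarchy(data.frame(
    granular_curie = c("ZP:0001129", "ZP:0010319", "ZP:0001130",
                       "ZP:0014550", "normal"),
    general_curie = c("ZP:0001129", "ZP:0001129", "ZP:0001129",
                      "ZP:0014550", "normal"),
    label = c("abnormal tail", "abnormally curved tail",
              "abnormally short tail", "abnormal snout", "normal"),
    stringsAsFactors = FALSE))
}

toy_lexicon <- function(hierarchy = toy_hierarchy()) {
  term_lexicon(data.frame(
    verbatim = c("curved tail", "bent tail", "C-tail", "short tail",
                 "malformation tail", "snout off", "normal"),
    curie = c("ZP:0010319", "ZP:0010319", "ZP:0010319", "ZP:0001130",
              "ZP:0001129", "ZP:0014550", "normal"),
    stringsAsFactors = FALSE), hierarchy)
}

toy_survey <- function(df, survey_id = "S1") {
  suppressMessages(suppressWarnings(survey_table(df, survey_id)))
}

# random survey table with n records over given axes (free text terms)
random_survey <- function(n, n_raters = 4, n_specimens = 3,
                          terms = c("curved tail", "bent tail",
                                    "short tail", "snout off", "normal")) {
  toy_survey(data.frame(
    rater = sample(sprintf("R%d", seq_len(n_raters)), n, replace = TRUE),
    specimen = sample(sprintf("L%d", seq_len(n_specimens)), n,
                      replace = TRUE),
    term = sample(terms, n, replace = TRUE),
    stringsAsFactors = FALSE))
}

# presence array built by hand from a rater x (specimen, trait) 0/1 vector
pattern_matrix <- function(bits, specimen = "s1", trait = "T") {
  n <- length(bits)
  m <- array(as.integer(bits), dim = c(n, 1, 1),
             dimnames = list(rater = sprintf("R%d", seq_len(n)),
                             specimen = specimen, trait = trait))
  m
}

# beta-binomial grouped binary data with latent ICC rho on the 0/1 scale:
# group probabilities p_i ~ Beta with mean mu and sum s = (1 - rho)/rho,
# giving Var(p)/ (Var(p) + E[p(1-p)]) = rho exactly.
sim_icc_groups <- function(n_groups, n_per, rho, mu = 0.5) {
  p <- if (rho <= 0) rep(mu, n_groups) else {
    s <- (1 - rho) / rho
    stats::rbeta(n_groups, mu * s, (1 - mu) * s)
  }
  list(values = stats::rbinom(n_groups * n_per, 1, rep(p, each = n_per)),
       groups = rep(seq_len(n_groups), each = n_per))
}

# align two harmonized tables onto shared axes and return concordance cells
paired_cells <- function(h1, h2, level = "general") {
  col <- if (level == "general") "general_curie" else "granular_curie"
  traits <- sort(union(unique(h1[[col]]), unique(h2[[col]])))
  raters <- sort(union(unique(h1$rater), unique(h2$rater)))
  specimens <- sort(union(unique(h1$specimen), unique(h2$specimen)))
  m1 <- presence_matrix(h1, level, raters, specimens, traits)
  m2 <- presence_matrix(h2, level, raters, specimens, traits)
  uni <- observed_universe(m1, m2)
  list(s1 = suppressMessages(concordance_cells(m1, uni)),
       s2 = suppressMessages(concordance_cells(m2, uni)),
       m1 = m1, m2 = m2)
}
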