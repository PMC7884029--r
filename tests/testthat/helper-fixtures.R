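# Shared fixture builders for the test suite. Everything is generated in
# code; no stored binary data.

# Small null cohort: no planted group effects, no modules, no survival
# shifts. Used for calibration checks.
null_config <- function(n_aptamers = 500, seed = 1, ...) {
  sim_config(n_aptamers = n_aptamers, frac_up = 0, frac_down = 0,
             n_modules = 0, n_survival_proteins = 0, seed = seed, ...)
}

# Cohort with strong planted fold changes (all |FC| >= 1.25) for recovery
# checks at the study's group sizes.
planted_config <- function(n_aptamers = 2000, n_planted = 150, seed = 1, ...) {
  sim_config(n_aptamers = n_aptamers,
             frac_up = (n_planted / 2) / n_aptamers,
             frac_down = (n_planted / 2) / n_aptamers,
             fc_up_range = c(1.25, 3.33), fc_up_median = 1.4,
             fc_down_range = c(0.56, 0.8), fc_down_median = 0.75,
             n_modules = 0, n_survival_proteins = 0, seed = seed, ...)
}

# Tiny hand-built study: n samples, m aptamers, deterministic values.
tiny_study <- function(n = 12, m = 4, seed = 42) {
  set.seed(seed)
  expr <- matrix(exp(rnorm(n * m, log(1000), 0.3)), n, m)
  ids <- sprintf("S%03d", seq_len(n))
  apt <- sprintf("%d-%d_1", 1000 + seq_len(m), seq_len(m))
  rownames(expr) <- ids
  colnames(expr) <- apt
  samples <- data.frame(
    sample_id = ids,
    group = rep(c("centenarian", "offspring", "control"), length.out = n),
    sex = rep(c("F", "M"), length.out = n),
    age_at_draw = seq(70, 105, length.out = n),
    collection_year = rep(2003:2008, length.out = n),
    survival_years = seq(0.5, 12, length.out = n),
    dead = rep(c(TRUE, FALSE), length.out = n),
    stringsAsFactors = FALSE
  )
  aptamers <- data.frame(aptamer_id = apt,
                         uniprot = sprintf("P%05d", seq_len(m)),
                         gene_symbol = sprintf("G%02d", seq_len(m)),
                         stringsAsFactors = FALSE)
  new_study(expr, samples, aptamers)
}

# Literal Benjamini-Hochberg step-up computed from the sorted definition:
# q_(i) = min_{j >= i} m p_(j) / j, clipped at 1, in input order.
bh_literal <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(m * p[o][i:m] / (i:m)))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Two-sided Fisher exact by direct enumeration with binomial-coefficient
# ratios (no dhyper): independent oracle for fisher_exact_2x2.
fisher_enum <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  if (n == 0) return(1)
  ks <- max(0, c1 - r2):min(r1, c1)
  probs <- choose(r1, ks) * choose(r2, c1 - ks) / choose(n, c1)
  obs <- probs[ks == a]
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}
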