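# 9-aptamer fixture with one aptamer engineered into each tier pair.
# p-values are chosen so that BH within the 9-aptamer intersection puts
# exactly three aptamers in each tier on each side.
tier_fixture <- function() {
  p_sig <- c(1e-8, 2e-8, 3e-8)      # q ~ 1e-7 << 0.01
  p_amb <- c(0.05, 0.06, 0.07)      # q ~ 0.1, p <= 0.2
  p_ns <- c(0.5, 0.7, 0.9)          # p > 0.2
  internal <- data.frame(
    aptamer_id = sprintf("A%d", 1:9),
    p = c(p_sig, p_amb, p_ns),
    effect_sign = rep(1L, 9),
    stringsAsFactors = FALSE
  )
  external <- data.frame(
    aptamer_id = sprintf("A%d", 1:9),
    p_value = c(p_sig[1], p_amb[1], p_ns[1],
                p_sig[2], p_amb[2], p_ns[2],
                p_sig[3], p_amb[3], p_ns[3]),
    effect_sign = rep(1L, 9),
    n_samples = 240L,
    stringsAsFactors = FALSE
  )
  list(internal = internal, external = external)
}

test_that("tier assignment partitions every (p, q) pair", {
  expect_equal(assign_tier(0.0001, 0.004), "significant")
  expect_equal(assign_tier(0.5, 0.7), "not_significant")
  expect_equal(assign_tier(0.05, 0.12), "ambiguous")
  set.seed(30)
  p <- runif(200)
  q <- pmin(1, p * runif(200, 1, 3))
  tiers <- assign_tier(p, q)
  expect_true(all(tiers %in% c("significant", "ambiguous",
                               "not_significant")))
  expect_length(tiers, 200)
})

test_that("cross-classification fills one aptamer per cell on the fixture", {
  fx <- tier_fixture()
  ct <- cross_classify(fx$internal, fx$external)
  expect_equal(as.vector(ct$table), rep(1L, 9), ignore_attr = TRUE)
  expect_equal(sum(ct$table), ct$n_overlap)
})

test_that("self-comparison has empty extreme concordance cells", {
  fx <- tier_fixture()
  ext_same <- data.frame(aptamer_id = fx$internal$aptamer_id,
                         p_value = fx$internal$p,
                         effect_sign = fx$internal$effect_sign,
                         n_samples = 240L)
  ct <- cross_classify(fx$internal, ext_same)
  expect_equal(ct$table["significant", "not_significant"], 0L,
               ignore_attr = TRUE)
  expect_equal(ct$table["not_significant", "significant"], 0L,
               ignore_attr = TRUE)
  # an external study with no signal leaves the significant column empty
  ext_flat <- ext_same
  ext_flat$p_value <- 0.9
  ct2 <- cross_classify(fx$internal, ext_flat)
  expect_equal(sum(ct2$table[, "significant"]), 0L, ignore_attr = TRUE)
  expect_error(cross_classify(fx$internal,
                              data.frame(aptamer_id = "ZZZ", p_value = 0.5,
                                         effect_sign = 1L)),
               "empty platform intersection")
})

test_that("sign concordance reproduces the published cross-platform test", {
  membership <- c(rep(TRUE, 186), rep(FALSE, 257))
  concordant <- c(rep(TRUE, 129), rep(FALSE, 57),
                  rep(TRUE, 128), rep(FALSE, 129))
  res <- sign_concordance_test(membership, concordant)
  expect_equal(signif(res$p_value, 1), 4e-5)
  expect_equal(unname(res$rates["members"]), 129 / 186, tolerance = 1e-12)
  # identical rates in both strata are uninformative
  res2 <- sign_concordance_test(rep(c(TRUE, FALSE), each = 100),
                                rep(c(TRUE, FALSE), 100))
  expect_equal(res2$p_value, 1)
})

test_that("sign concordance p-values are uniform under the null", {
  set.seed(31)
  ps <- replicate(200, {
    sign_concordance_test(runif(120) < 0.4, runif(120) < 0.5)$p_value
  })
  # discrete test: p-values are conservative, never anti-conservative
  expect_gt(mean(ps > 0.5), 0.35)
  expect_lt(mean(ps < 0.05), 0.08)
})

test_that("derived signatures match constructed truth and stay disjoint", {
  fx <- tier_fixture()
  ct <- cross_classify(fx$internal, fx$external)
  sigs <- derive_signatures(ct$data)
  expect_equal(sigs$replicated, "A1")         # significant x significant
  expect_equal(sigs$extreme_old_age, "A3")    # int significant, ext ns
  expect_equal(sigs$immune_senescence, "A7")  # ext significant, int ns
  expect_length(sigs$discordant, 0)
  # discordant signs exclude an aptamer from the replicated set
  ext2 <- fx$external
  ext2$effect_sign[1] <- -1L
  sigs2 <- derive_signatures(cross_classify(fx$internal, ext2)$data)
  expect_length(sigs2$replicated, 0)
  expect_equal(sigs2$discordant, "A1")
  # pairwise disjointness on random fixtures
  set.seed(32)
  for (i in 1:5) {
    internal <- data.frame(aptamer_id = sprintf("R%03d", 1:200),
                           p = runif(200)^2,
                           effect_sign = sample(c(-1L, 1L), 200, TRUE))
    external <- data.frame(aptamer_id = sprintf("R%03d", 1:200),
                           p_value = runif(200)^2,
                           effect_sign = sample(c(-1L, 1L), 200, TRUE),
                           n_samples = 100L)
    s <- derive_signatures(cross_classify(internal, external)$data)
    expect_length(intersect(s$replicated, s$extreme_old_age), 0)
    expect_length(intersect(s$replicated, s$immune_senescence), 0)
    expect_length(intersect(s$extreme_old_age, s$immune_senescence), 0)
  }
})

test_that("meta-analysis reinforces concordant and cancels discordant", {
  internal <- data.frame(aptamer_id = c("A", "B"), p = c(0.01, 0.01),
                         effect_sign = c(1L, 1L))
  external <- data.frame(aptamer_id = c("A", "B"), p_value = c(0.01, 0.01),
                         effect_sign = c(1L, -1L), n_samples = 224L)
  m <- meta_analyze(internal, external, n_internal = 224)
  recA <- m$records[m$records$aptamer_id == "A", ]
  recB <- m$records[m$records$aptamer_id == "B", ]
  expect_lt(recA$p, 0.01)
  expect_equal(recB$p, 1, tolerance = 1e-12)
  expect_error(meta_analyze(internal, external[, -4], n_internal = 224),
               "sample size")
})

test_that("meta-analysis of weak concordant effects beats either study", {
  gains <- vapply(1:3, function(s) {
    cfg <- sim_config(n_aptamers = 1000, frac_up = 0.1, frac_down = 0.1,
                      fc_up_range = c(1.25, 1.26), fc_up_median = 1.255,
                      fc_down_range = c(0.79, 0.8), fc_down_median = 0.795,
                      n_modules = 0, n_survival_proteins = 0, seed = s)
    truth <- simulate_cohort(cfg)$truth
    e1 <- simulate_external_study(truth, 100, noise_sd = 0.5, seed = 2 * s)
    e2 <- simulate_external_study(truth, 100, noise_sd = 0.5,
                                  seed = 2 * s + 1)
    m <- meta_analyze(e1, e2, n_internal = 100)
    length(m$significant) /
      max(m$n_single_internal, m$n_single_external, 1)
  }, numeric(1))
  expect_gt(mean(gains), 2)
})

test_that("replication union tracks provenance and matches enumeration", {
  ru <- replication_union(list(s1 = c("a", "b"), s2 = c("b", "c")))
  expect_equal(ru$union, c("a", "b", "c"))
  expect_true(ru$provenance["b", "s1"] && ru$provenance["b", "s2"])
  expect_equal(replication_union(list(s1 = character(0)))$n_aptamers, 0)
  set.seed(33)
  for (i in 1:5) {
    sets <- lapply(1:3, function(j) sample(sprintf("x%02d", 1:40),
                                           sample(5:20, 1)))
    names(sets) <- paste0("st", 1:3)
    ru <- replication_union(sets)
    expect_equal(ru$n_aptamers, length(Reduce(union, sets)))
    expect_equal(sum(ru$provenance), sum(lengths(sets)))
  }
})

test_that("consistency filtering drops sign flips and non-significant hits", {
  external <- data.frame(aptamer_id = sprintf("E%d", 1:6),
                         effect_sign = c(1L, 1L, -1L, 1L, -1L, 1L),
                         p_value = c(1e-7, 1e-7, 1e-7, 1e-7, 1e-7, 0.8))
  reference <- data.frame(aptamer_id = sprintf("E%d", 1:6),
                          effect_sign = c(1L, 1L, -1L, -1L, -1L, 1L))
  out <- filter_interval_style(external, reference)
  # E4 flips sign against the reference, E6 is not significant
  expect_setequal(out$aptamer_id, c("E1", "E2", "E3", "E5"))
  # all-concordant, all-significant input passes unchanged
  out2 <- filter_interval_style(external[1:3, ], reference[1:3, ])
  expect_equal(out2$aptamer_id, external$aptamer_id[1:3])
})
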