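test_that("correlations match hand-computed Pearson values", {
  # 3 aptamers x 12 samples, fixed values, hand formula as oracle
  st <- tiny_study(n = 12, m = 3, seed = 63)
  r <- correlation_matrix(st, st$samples$sample_id)
  L <- log(st$expression)
  pearson <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  for (i in 1:3) for (j in 1:3) {
    expect_equal(r[i, j], if (i == j) 1 else pearson(L[, i], L[, j]),
                 tolerance = 1e-12)
  }
})

test_that("duplicated aptamers correlate perfectly, flat ones get zero", {
  st <- tiny_study(n = 15, m = 4)
  ex <- st$expression
  ex[, 2] <- ex[, 1]
  ex[, 4] <- 500
  st2 <- new_study(ex, st$samples, st$aptamers)
  expect_warning(r <- correlation_matrix(st2, st2$samples$sample_id),
                 "zero-variance")
  expect_equal(r[1, 2], 1, tolerance = 1e-12)
  expect_equal(r[1, 4], 0)
  expect_equal(diag(r), rep(1, 4), ignore_attr = TRUE)
  expect_error(correlation_matrix(st, st$samples$sample_id[1:5]),
               "at least 10")
})

test_that("independent aptamers stay weakly correlated at n = 500", {
  cfg <- null_config(n_aptamers = 60, seed = 64, n_centenarians = 500,
                     n_offspring = 5, n_controls = 5)
  sim <- simulate_cohort(cfg)
  cent <- sim$study$samples$sample_id[sim$study$samples$group == "centenarian"]
  r <- correlation_matrix(sim$study, cent)
  off <- abs(r[upper.tri(r)])
  expect_gt(mean(off < 0.2), 0.99)
})

test_that("soft-threshold adjacency behaves monotonically", {
  set.seed(65)
  r <- cor(matrix(rnorm(40 * 30), 40, 30))
  st <- soft_threshold_select(r)
  expect_true(st$power %in% 1:12)
  expect_true(all(diff(st$fit_table$mean_adjacency) <= 1e-12))
  # a binary correlation fixture at beta = 1 leaves |r| unchanged
  rb <- diag(10)
  rb[1, 2] <- rb[2, 1] <- 1
  expect_equal(abs(rb)^1, abs(rb))
})

test_that("soft threshold separates planted blocks from background", {
  sim <- simulate_cohort(sim_config(n_aptamers = 120, frac_up = 0,
                                    frac_down = 0, n_modules = 2,
                                    module_size_range = c(30, 30),
                                    n_survival_proteins = 0, seed = 66))
  cent <- sim$study$samples$sample_id[sim$study$samples$group == "centenarian"]
  r <- correlation_matrix(sim$study, cent)
  st <- soft_threshold_select(r)
  A <- abs(r)^st$power
  tm <- sim$truth$aptamers$module
  names(tm) <- sim$truth$aptamers$aptamer_id
  ids <- colnames(A)
  within <- A[tm[ids] == 1, tm[ids] == 1]
  between <- A[tm[ids] == 1, tm[ids] == 0]
  expect_gt(median(within[upper.tri(within)]) / median(between), 10)
})

test_that("topological overlap matches the hand-evaluated formula", {
  # two connected nodes, nothing else: TOM = 1
  A <- matrix(0, 3, 3)
  A[1, 2] <- A[2, 1] <- 1
  tom <- topological_overlap(A)
  expect_equal(tom[1, 2], 1)
  # 4-node hand example evaluated with explicit loops
  A <- matrix(c(0, .5, .2, 0,
                .5, 0, .4, .1,
                .2, .4, 0, .3,
                0, .1, .3, 0), 4, 4, byrow = TRUE)
  tom <- topological_overlap(A)
  k <- rowSums(A)
  for (i in 1:4) for (j in 1:4) {
    if (i == j) {
      expect_equal(tom[i, j], 1)
    } else {
      shared <- sum(A[i, ] * A[, j])
      expect_equal(tom[i, j],
                   (shared + A[i, j]) / (min(k[i], k[j]) + 1 - A[i, j]),
                   tolerance = 1e-12)
    }
  }
  # values stay in [0, 1] on random adjacencies
  set.seed(67)
  for (rep in 1:3) {
    R <- matrix(runif(100), 10, 10)
    R <- (R + t(R)) / 2
    diag(R) <- 0
    tom <- topological_overlap(R)
    expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
  }
  expect_error(topological_overlap(matrix(runif(9), 3, 3)), "symmetric")
})

test_that("planted modules are recovered with high adjusted Rand index", {
  skip_if_not_installed("mclust")
  ari <- vapply(1:5, function(s) {
    cfg <- sim_config(n_aptamers = 200, frac_up = 0, frac_down = 0,
                      n_modules = 2, module_size_range = c(30, 30),
                      n_survival_proteins = 0, seed = s)
    sim <- simulate_cohort(cfg)
    ms <- build_module_set(sim$study, "centenarian", label = "CENT")
    tm <- sim$truth$aptamers$module
    names(tm) <- sim$truth$aptamers$aptamer_id
    mclust::adjustedRandIndex(tm, ms$labels[names(tm)])
  }, numeric(1))
  expect_gte(mean(ari), 0.9)
})

test_that("pure noise yields only the null module", {
  n_mod <- vapply(1:5, function(s) {
    sim <- simulate_cohort(null_config(n_aptamers = 150, seed = 100 + s))
    ms <- build_module_set(sim$study, "centenarian")
    # membership + null module partition the universe
    all_ids <- c(unlist(ms$modules), ms$null_module)
    expect_setequal(all_ids, sim$study$aptamers$aptamer_id)
    expect_equal(length(all_ids), ncol(sim$study$expression))
    length(ms$modules)
  }, integer(1))
  expect_gte(mean(n_mod == 0), 0.9)
})

test_that("module sizes respect the minimum and a degenerate TOM is null", {
  sim <- simulate_cohort(sim_config(n_aptamers = 150, frac_up = 0,
                                    frac_down = 0, n_modules = 3,
                                    module_size_range = c(25, 35),
                                    n_survival_proteins = 0, seed = 68))
  ms <- build_module_set(sim$study, "centenarian")
  if (length(ms$modules) > 0) {
    expect_true(all(vapply(ms$modules, length, integer(1)) >= 20))
  }
  flat <- matrix(0.5, 20, 20)
  diag(flat) <- 1
  det <- detect_modules(flat)
  expect_length(det$modules, 0)
  expect_length(det$null_module, 20)
})

test_that("eigengenes summarize modules with the documented conventions", {
  sim <- simulate_cohort(sim_config(n_aptamers = 80, frac_up = 0,
                                    frac_down = 0, n_modules = 1,
                                    module_size_range = c(25, 25),
                                    module_latent_sd = 0.5,
                                    n_survival_proteins = 0, seed = 69))
  st <- sim$study
  cent <- st$samples$sample_id[st$samples$group == "centenarian"]
  members <- sim$truth$aptamers$aptamer_id[sim$truth$aptamers$module == 1]
  e <- module_eigengene(st, members, cent)
  expect_equal(sd(e), 1, tolerance = 1e-12)
  Z <- scale(log(st$expression[cent, members]))
  expect_gte(cor(e, rowMeans(Z)), 0)
  # explained variance equals the leading eigenvalue share
  sv <- svd(Z)
  share_svd <- sv$d[1]^2 / sum(sv$d^2)
  share_eig <- eigen(cov(Z))$values[1] * (nrow(Z) - 1) /
    sum(Z^2)
  expect_equal(share_svd, share_eig, tolerance = 1e-10)
  # a rank-1 module: |cor(eigengene, member z)| = 1 for every member
  ex <- st$expression
  base <- ex[, members[1]]
  for (mm in members) ex[, mm] <- base * runif(1, 0.5, 2)
  st2 <- new_study(ex, st$samples, st$aptamers)
  e2 <- module_eigengene(st2, members, cent)
  Z2 <- scale(log(st2$expression[cent, members]))
  expect_true(all(abs(cor(e2, Z2)) > 1 - 1e-10))
})

test_that("module group differences are antisymmetric and signed right", {
  sim <- simulate_cohort(sim_config(n_aptamers = 60, frac_up = 0,
                                    frac_down = 0, n_modules = 1,
                                    module_size_range = c(20, 20),
                                    n_survival_proteins = 0, seed = 70))
  st <- sim$study
  members <- sim$truth$aptamers$aptamer_id[sim$truth$aptamers$module == 1]
  cent <- st$samples$sample_id[st$samples$group == "centenarian"]
  young <- setdiff(st$samples$sample_id, cent)
  d1 <- module_group_difference(st, members, cent, young)
  d2 <- module_group_difference(st, members, young, cent)
  expect_equal(d1, -d2, tolerance = 1e-12)
  expect_lt(abs(d1), 0.25)  # no planted shift
  # a planted +0.5 sd shift in centenarians turns the score positive
  ex <- st$expression
  ex[cent, members] <- ex[cent, members] * exp(0.5 * 0.25)
  st2 <- new_study(ex, st$samples, st$aptamers)
  expect_gt(module_group_difference(st2, members, cent, young), 0)
})

test_that("the cross-group module graph follows the edge rules", {
  sim <- simulate_cohort(sim_config(n_aptamers = 200, frac_up = 0,
                                    frac_down = 0, n_modules = 3,
                                    module_size_range = c(25, 40),
                                    n_survival_proteins = 0, seed = 71))
  a <- build_module_set(sim$study, "centenarian", label = "CENT")
  b <- build_module_set(sim$study, c("offspring", "control"),
                        label = "CTRL")
  g <- build_module_graph(a, b)
  # brute-force Jaccard tally as the oracle for the edge set
  expected <- 0
  for (ma in a$modules) for (mb in b$modules) {
    j <- length(intersect(ma, mb)) / length(union(ma, mb))
    if (j > 0.10) expected <- expected + 1
  }
  expect_equal(nrow(g$cross_edges), expected)
  expect_true(all(g$cross_edges$jaccard > 0.10))
  # identical module sets connect every module with Jaccard 1
  g2 <- build_module_graph(a, a)
  expect_equal(sum(g2$cross_edges$jaccard == 1), length(a$modules))
  # disjoint memberships yield no cross edges
  b_disjoint <- b
  b_disjoint$modules <- list(MX = setdiff(sim$study$aptamers$aptamer_id,
                                          unlist(a$modules))[1:25])
  b_disjoint$avg_std_diff <- c(MX = 0)
  b_disjoint$eigengenes <- NULL
  g3 <- build_module_graph(a, b_disjoint)
  expect_equal(nrow(g3$cross_edges), 0)
})
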