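# Synthetic cohort generator with a ground-truth ledger.
#
# The generator plants, on the log-RFU scale, (i) centenarian fold changes
# drawn inside the observed up/down ranges, (ii) additive sex and
# collection-year covariate effects so the adjusted models are correctly
# specified, (iii) coherent correlated-protein modules through Gaussian
# latent factors with shared-sign loadings, and (iv) a latent binary
# survival class per sample whose observed survival years straddle the
# 2-year / 10-year cutoffs used by the survival signatures.

#' Simulation configuration
#'
#' Defaults emulate the study cohort: 77 centenarians, 82 offspring and 65
#' controls; mean ages at draw 105.7/71.2/70.6 years; 66/66/55 percent
#' female; 4785 aptamers with 733 planted up (fold change 1.02-3.33, median
#' 1.26) and 695 planted down (0.56-0.97, median 0.88) in centenarians.
#'
#' @param n_centenarians,n_offspring,n_controls group sizes.
#' @param female_fraction per-group proportion female (centenarian,
#'   offspring, control).
#' @param age_mean,age_sd per-group age-at-draw mean and SD, years.
#' @param n_aptamers number of aptamers on the simulated platform.
#' @param frac_up,frac_down proportion of aptamers planted higher / lower in
#'   centenarians; `frac_up + frac_down <= 1`.
#' @param fc_up_range,fc_up_median fold-change interval (> 1) and target
#'   median for planted-up aptamers; draws follow a truncated exponential on
#'   the log scale so the median falls near the target.
#' @param fc_down_range,fc_down_median analogous interval inside (0, 1).
#' @param residual_sd_log SD of Gaussian log-RFU noise (unitless log scale).
#' @param sex_effect_sd,year_effect_sd SD of the per-aptamer additive female
#'   shift and of the per-aptamer linear collection-year slope (log-RFU per
#'   year).
#' @param n_modules,module_size_range,module_latent_sd number of planted
#'   co-expression modules, their size interval, and the loading scale tying
#'   members to the per-sample Gaussian latent factor.
#' @param n_survival_proteins,survival_effect_log number of aptamers with a
#'   planted survival-class shift and its log-RFU magnitude (random sign).
#' @param frac_short_survival per-group probability of the short-survival
#'   latent class (centenarian, offspring, control).
#' @param frac_missing_followup proportion of offspring/control samples with
#'   follow-up too short to label.
#' @param collection_years calendar years samples are drawn from.
#' @param seed integer RNG seed; fixes every emitted artifact bit-for-bit.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_centenarians = 77, n_offspring = 82, n_controls = 65,
                       female_fraction = c(0.66, 0.66, 0.55),
                       age_mean = c(105.7, 71.2, 70.6),
                       age_sd = c(3.6, 9.3, 7.8),
                       n_aptamers = 4785,
                       frac_up = 733 / 4785, frac_down = 695 / 4785,
                       fc_up_range = c(1.02, 3.33), fc_up_median = 1.26,
                       fc_down_range = c(0.56, 0.97), fc_down_median = 0.88,
                       residual_sd_log = 0.25,
                       sex_effect_sd = 0.05, year_effect_sd = 0.01,
                       n_modules = 10, module_size_range = c(20, 480),
                       module_latent_sd = 0.3,
                       n_survival_proteins = 40, survival_effect_log = 0.3,
                       frac_short_survival = c(0.55, 0.3, 0.3),
                       frac_missing_followup = 0.05,
                       collection_years = 2003:2016,
                       seed = 1L) {
  cfg <- list(n_centenarians = n_centenarians, n_offspring = n_offspring,
              n_controls = n_controls, female_fraction = female_fraction,
              age_mean = age_mean, age_sd = age_sd, n_aptamers = n_aptamers,
              frac_up = frac_up, frac_down = frac_down,
              fc_up_range = fc_up_range, fc_up_median = fc_up_median,
              fc_down_range = fc_down_range, fc_down_median = fc_down_median,
              residual_sd_log = residual_sd_log,
              sex_effect_sd = sex_effect_sd, year_effect_sd = year_effect_sd,
              n_modules = n_modules, module_size_range = module_size_range,
              module_latent_sd = module_latent_sd,
              n_survival_proteins = n_survival_proteins,
              survival_effect_log = survival_effect_log,
              frac_short_survival = frac_short_survival,
              frac_missing_followup = frac_missing_followup,
              collection_years = collection_years,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  counts <- c(cfg$n_centenarians, cfg$n_offspring, cfg$n_controls,
              cfg$n_aptamers)
  if (any(counts <= 0)) stop2("all counts must be positive")
  props <- c(cfg$female_fraction, cfg$frac_up, cfg$frac_down,
             cfg$frac_short_survival, cfg$frac_missing_followup)
  if (any(props < 0 | props > 1)) stop2("proportions must lie in [0, 1]")
  if (cfg$frac_up + cfg$frac_down > 1) stop2("frac_up + frac_down exceeds 1")
  if (cfg$fc_up_range[1] <= 1) stop2("fc_up_range must lie above 1")
  if (cfg$fc_down_range[1] <= 0 || cfg$fc_down_range[2] >= 1) {
    stop2("fc_down_range must lie inside (0, 1)")
  }
  if (cfg$n_modules > 0 &&
      cfg$n_modules * cfg$module_size_range[1] > cfg$n_aptamers) {
    stop2("planted module sizes exceed n_aptamers")
  }
  if (cfg$residual_sd_log <= 0) stop2("residual_sd_log must be positive")
  invisible(cfg)
}

# Draw fold changes from a truncated exponential on the log scale so the
# median lands near `med` while all values stay inside `range`.
draw_fc <- function(n, range, med, up = TRUE) {
  if (n == 0) return(numeric(0))
  if (up) {
    lo <- log(range[1]); hi <- log(range[2]); m <- log(med) - lo
  } else {
    lo <- log(1 / range[2]); hi <- log(1 / range[1]); m <- log(1 / med) - lo
  }
  rate <- log(2) / max(m, 1e-6)
  cap <- stats::pexp(hi - lo, rate)
  x <- lo + stats::qexp(stats::runif(n, 0, cap), rate)
  fc <- exp(x)
  if (up) fc else 1 / fc
}

make_aptamer_table <- function(n_aptamers, dup_fraction = 0.12) {
  n_dup <- floor(n_aptamers * dup_fraction)
  n_sym <- n_aptamers - n_dup
  symbols <- sprintf("GENE%04d", seq_len(n_sym))
  gene_symbol <- c(symbols,
                   if (n_dup > 0) sample(symbols, n_dup, replace = n_dup > n_sym))
  gene_symbol <- sample(gene_symbol)
  data.frame(
    aptamer_id = sprintf("%d-%d_%d",
                         sample(1000:14999, n_aptamers, replace = FALSE),
                         sample(1:99, n_aptamers, replace = TRUE),
                         sample(1:4, n_aptamers, replace = TRUE)),
    uniprot = sprintf("P%05d", sample(10000:99999, n_aptamers)),
    gene_symbol = gene_symbol,
    stringsAsFactors = FALSE
  )
}

#' Simulate a centenarian-study cohort with ground truth
#'
#' Generates a strictly positive samples-by-aptamers RFU matrix whose log
#' has the additive structure assumed by the downstream analyses:
#' per-aptamer baseline + centenarian fold-change shift + sex and
#' collection-year covariate terms + module latent contribution + survival
#' class shift + Gaussian noise.
#'
#' @param config a [sim_config()].
#' @return list with `study` (a [new_study()] object), and `truth` (the
#'   ground-truth ledger: per-aptamer `planted_direction`, `planted_fc`,
#'   `module`, `survival_effect`; per-sample `group` and `survival_class`).
#' @export
simulate_cohort <- function(config = sim_config()) {
  validate_sim_config(config)
  set.seed(config$seed)
  cfg <- config

  ## samples -----------------------------------------------------------
  grp_n <- c(centenarian = cfg$n_centenarians, offspring = cfg$n_offspring,
             control = cfg$n_controls)
  n <- sum(grp_n)
  group <- factor(rep(names(grp_n), grp_n), levels = GROUP_LEVELS)
  sample_id <- sprintf("S%04d", seq_len(n))
  sex <- unlist(lapply(seq_along(grp_n), function(g) {
    nf <- round(grp_n[g] * cfg$female_fraction[g])
    sample(c(rep("F", nf), rep("M", grp_n[g] - nf)))
  }))
  age <- unlist(lapply(seq_along(grp_n), function(g) {
    a <- stats::rnorm(grp_n[g], cfg$age_mean[g], cfg$age_sd[g])
    pmax(a, if (g == 1) 92 else 45)
  }))
  year <- sample(cfg$collection_years, n, replace = TRUE)

  # latent survival class and observed follow-up straddling the cutoffs
  p_short <- cfg$frac_short_survival[as.integer(group)]
  surv_class <- ifelse(stats::runif(n) < p_short, "short", "long")
  survival_years <- numeric(n)
  dead <- logical(n)
  cent <- group == "centenarian"
  i <- cent & surv_class == "short"
  survival_years[i] <- stats::runif(sum(i), 0.1, 1.9); dead[i] <- TRUE
  i <- cent & surv_class == "long"
  survival_years[i] <- stats::runif(sum(i), 2.1, 8)
  dead[i] <- stats::runif(sum(i)) < 0.94
  i <- !cent & surv_class == "short"
  survival_years[i] <- stats::runif(sum(i), 1, 9.9); dead[i] <- TRUE
  i <- !cent & surv_class == "long"
  survival_years[i] <- stats::runif(sum(i), 10.5, 16)
  dead[i] <- stats::runif(sum(i)) < 0.25
  # a fraction of younger samples have follow-up too short to label
  i <- which(!cent & stats::runif(n) < cfg$frac_missing_followup & !dead)
  if (length(i) > 0) {
    survival_years[i] <- NA_real_
  }
  samples <- data.frame(sample_id = sample_id, group = as.character(group),
                        sex = sex, age_at_draw = round(age, 1),
                        collection_year = year,
                        survival_years = round(survival_years, 2),
                        dead = dead, stringsAsFactors = FALSE)

  ## aptamers and planted effects --------------------------------------
  aptamers <- make_aptamer_table(cfg$n_aptamers)
  m <- cfg$n_aptamers
  n_up <- round(cfg$frac_up * m)
  n_down <- round(cfg$frac_down * m)
  direction <- rep("null", m)
  idx <- sample(m, n_up + n_down)
  direction[idx[seq_len(n_up)]] <- "up"
  if (n_down > 0) direction[idx[n_up + seq_len(n_down)]] <- "down"
  planted_fc <- rep(1, m)
  planted_fc[direction == "up"] <- draw_fc(n_up, cfg$fc_up_range,
                                           cfg$fc_up_median, up = TRUE)
  planted_fc[direction == "down"] <- draw_fc(n_down, cfg$fc_down_range,
                                             cfg$fc_down_median, up = FALSE)

  module <- rep(0L, m)
  if (cfg$n_modules > 0) {
    sizes <- sample(cfg$module_size_range[1]:cfg$module_size_range[2],
                    cfg$n_modules, replace = TRUE)
    sizes <- pmin(sizes, floor(m / cfg$n_modules))
    sizes <- pmax(sizes, cfg$module_size_range[1])
    if (sum(sizes) > m) stop2("planted module sizes exceed n_aptamers")
    free <- sample(m)
    off <- 0L
    for (k in seq_len(cfg$n_modules)) {
      module[free[off + seq_len(sizes[k])]] <- k
      off <- off + sizes[k]
    }
  }

  survival_effect <- rep(0, m)
  if (cfg$n_survival_proteins > 0) {
    sv <- sample(m, min(cfg$n_survival_proteins, m))
    survival_effect[sv] <- cfg$survival_effect_log *
      sample(c(-1, 1), length(sv), replace = TRUE)
  }

  ## expression matrix --------------------------------------------------
  baseline <- stats::rnorm(m, log(5000), 0.8)
  beta_sex <- stats::rnorm(m, 0, cfg$sex_effect_sd)
  beta_year <- stats::rnorm(m, 0, cfg$year_effect_sd)
  year_c <- year - mean(cfg$collection_years)

  logY <- matrix(stats::rnorm(n * m, 0, cfg$residual_sd_log), n, m)
  logY <- logY + rep(baseline, each = n)
  logY <- logY + as.numeric(cent) %o% log(planted_fc)
  logY <- logY + as.numeric(sex == "F") %o% beta_sex
  logY <- logY + year_c %o% beta_year
  # survival indicator centered within group: the short-survival class is
  # more common in centenarians, so an uncentered shift would leak into the
  # group contrast and mislabel survival aptamers as group effects
  long_ind <- as.numeric(surv_class == "long")
  long_ctr <- long_ind - stats::ave(long_ind, group)
  logY <- logY + long_ctr %o% survival_effect
  if (cfg$n_modules > 0 && cfg$module_latent_sd > 0) {
    for (k in seq_len(cfg$n_modules)) {
      members <- which(module == k)
      f <- stats::rnorm(n)                 # per-sample latent factor
      # shared-sign loadings keep the module coherent for eigengene summaries
      load <- cfg$module_latent_sd * stats::runif(length(members), 0.7, 1.3)
      logY[, members] <- logY[, members] + f %o% load
    }
  }
  expr <- exp(logY)
  rownames(expr) <- sample_id
  colnames(expr) <- aptamers$aptamer_id

  truth <- list(
    aptamers = data.frame(aptamer_id = aptamers$aptamer_id,
                          gene_symbol = aptamers$gene_symbol,
                          planted_direction = direction,
                          planted_fc = planted_fc,
                          module = module,
                          survival_effect = survival_effect,
                          stringsAsFactors = FALSE),
    samples = data.frame(sample_id = sample_id,
                         group = as.character(group),
                         survival_class = surv_class,
                         stringsAsFactors = FALSE),
    config = cfg
  )
  list(study = new_study(expr, samples, aptamers), truth = truth)
}

#' Simulate an external aging study's summary table
#'
#' Emulates a partner cohort sharing the aptamer platform: each aptamer gets
#' a signed z drawn around the attenuation-scaled planted log fold change,
#' z ~ N(attenuation * log(fc) * sqrt(n) / (2 * noise_sd), 1), the mean a
#' balanced two-arm design would give. `attenuation = 0` yields a null study
#' with uniform p-values.
#'
#' @param truth truth ledger from [simulate_cohort()].
#' @param n_samples external study sample size (weighting and power).
#' @param attenuation effect-size scaling in \[0, 1\].
#' @param noise_sd per-observation SD of the emulated external measurement.
#' @param seed RNG seed.
#' @param overlap_ids optional aptamer ids restricting to a platform overlap.
#' @return data.frame with `aptamer_id`, `gene_symbol`, `effect_sign`,
#'   `z`, `p_value`, `n_samples`.
#' @export
simulate_external_study <- function(truth, n_samples, attenuation = 1,
                                    noise_sd = 0.25, seed = 1L,
                                    overlap_ids = NULL) {
  if (attenuation < 0 || attenuation > 1) stop2("attenuation must be in [0, 1]")
  if (noise_sd <= 0) stop2("noise_sd must be positive")
  set.seed(as.integer(seed))
  apt <- truth$aptamers
  theta <- log(apt$planted_fc)
  mu <- attenuation * theta * sqrt(n_samples) / (2 * noise_sd)
  z <- stats::rnorm(nrow(apt), mu, 1)
  out <- data.frame(aptamer_id = apt$aptamer_id,
                    gene_symbol = apt$gene_symbol,
                    effect_sign = ifelse(z >= 0, 1L, -1L),
                    z = z,
                    p_value = 2 * stats::pnorm(-abs(z)),
                    n_samples = as.integer(n_samples),
                    stringsAsFactors = FALSE)
  if (!is.null(overlap_ids)) out <- out[out$aptamer_id %in% overlap_ids, ]
  rownames(out) <- NULL
  out
}

#' Build fixture gene-set collections from the truth ledger
#'
#' Emits sets enriched for planted-up genes, planted-down genes and each
#' planted module, plus random decoy sets, as a GMT-serializable named list.
#' `contamination` replaces that fraction of each themed set with random
#' genes; at 1 membership is independent of the truth.
#'
#' @param truth truth ledger from [simulate_cohort()].
#' @param n_sets total number of sets.
#' @param set_size_range integer interval of set sizes.
#' @param contamination proportion of themed-set members drawn at random.
#' @param seed RNG seed.
#' @return named list of character vectors of gene symbols
#'   (class `gene_set_collection`).
#' @export
make_fixture_gene_sets <- function(truth, n_sets = 20,
                                   set_size_range = c(15, 100),
                                   contamination = 0.2, seed = 1L) {
  if (contamination < 0 || contamination > 1) {
    stop2("contamination must be in [0, 1]")
  }
  set.seed(as.integer(seed))
  apt <- truth$aptamers
  all_genes <- unique(apt$gene_symbol)
  if (set_size_range[2] > length(all_genes)) {
    stop2("set sizes exceed the number of aptamer gene symbols")
  }
  pools <- list(up = unique(apt$gene_symbol[apt$planted_direction == "up"]),
                down = unique(apt$gene_symbol[apt$planted_direction == "down"]))
  for (k in setdiff(unique(apt$module), 0L)) {
    pools[[paste0("module", k)]] <- unique(apt$gene_symbol[apt$module == k])
  }
  pools <- Filter(function(p) length(p) >= 3, pools)
  sets <- list()
  themes <- names(pools)
  for (i in seq_len(n_sets)) {
    size <- sample(set_size_range[1]:set_size_range[2], 1)
    themed <- length(themes) > 0 && i <= length(themes)
    if (themed) {
      pool <- pools[[themes[i]]]
      n_core <- min(round(size * (1 - contamination)), length(pool))
      core <- sample(pool, n_core)
      filler <- sample(setdiff(all_genes, core), size - n_core)
      members <- c(core, filler)
      nm <- paste0("SET_", toupper(themes[i]))
    } else {
      members <- sample(all_genes, size)
      nm <- sprintf("SET_DECOY%02d", i)
    }
    sets[[nm]] <- sort(unique(members))
  }
  structure(sets, class = "gene_set_collection")
}
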