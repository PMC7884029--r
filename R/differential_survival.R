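# Centenarian differential signature, offspring-vs-control contrast,
# survival-dichotomized signatures and direction-pattern classification.

#' Per-aptamer fold change between two groups
#'
#' FC = exp(mean log-RFU in numerator group - mean log-RFU in denominator
#' group): the ratio of geometric means. With the reporting convention used
#' throughout, FC of controls versus centenarians > 1 marks a protein that
#' is lower in centenarians.
#'
#' @param study a `cent_study`.
#' @param numerator_group,denominator_group group labels.
#' @return named numeric vector of fold changes per aptamer.
#' @export
compute_fold_change <- function(study, numerator_group, denominator_group) {
  g <- study$samples$group
  num <- g == numerator_group
  den <- g == denominator_group
  if (!any(num)) stop2("empty numerator group: ", numerator_group)
  if (!any(den)) stop2("empty denominator group: ", denominator_group)
  L <- log_expr(study)
  exp(colMeans(L[num, , drop = FALSE]) - colMeans(L[den, , drop = FALSE]))
}

diff_covariates <- function(samples, year_as_factor = FALSE) {
  data.frame(sex = factor(samples$sex),
             collection_year = if (year_as_factor) {
               factor(samples$collection_year)
             } else as.numeric(samples$collection_year))
}

#' Centenarian differential signature
#'
#' Per-aptamer ANOVA F-test of log-RFU across the three groups, adjusted
#' for sex and collection year, with Benjamini-Hochberg control across all
#' aptamers. The signature is the q < `fdr` set; direction is called from
#' the covariate-adjusted group means: "up_in_centenarians" only when the
#' adjusted centenarian mean exceeds both younger groups' means (and "down"
#' when below both); discordant significant aptamers are flagged "mixed".
#'
#' @param study a `cent_study` containing all three groups.
#' @param fdr signature FDR threshold (default 0.01).
#' @param year_as_factor model collection year as categorical batches
#'   instead of a linear term.
#' @return list with `records` (per-aptamer data.frame: F, p, q, both fold
#'   changes, effect sign, direction), `up`, `down`, `mixed` aptamer-id
#'   sets, and aptamer/unique-protein signature counts.
#' @export
centenarian_signature <- function(study, fdr = 0.01, year_as_factor = FALSE) {
  g <- as_group_factor(study$samples$group)
  if (nlevels(droplevels(g)) != 3) stop2("all three groups are required")
  covs <- diff_covariates(study$samples, year_as_factor)
  fit <- anova_f_matrix(log_expr(study), g, covs)
  q <- bh_adjust(fit$p)
  gm <- fit$group_means                          # 3 x m adjusted means
  d_cont <- gm["centenarian", ] - gm["control", ]
  d_off <- gm["centenarian", ] - gm["offspring", ]
  sig <- q < fdr
  direction <- rep("null", ncol(gm))
  direction[sig & d_cont > 0 & d_off > 0] <- "up_in_centenarians"
  direction[sig & d_cont < 0 & d_off < 0] <- "down_in_centenarians"
  direction[sig & direction == "null"] <- "mixed"
  records <- data.frame(
    aptamer_id = study$aptamers$aptamer_id,
    gene_symbol = study$aptamers$gene_symbol,
    F = fit$F, p = fit$p, q = q,
    fc_cont_vs_cent = compute_fold_change(study, "control", "centenarian"),
    fc_off_vs_cent = compute_fold_change(study, "offspring", "centenarian"),
    effect_sign = ifelse((d_cont + d_off) / 2 >= 0, 1L, -1L),
    direction = direction,
    stringsAsFactors = FALSE
  )
  rownames(records) <- NULL
  sig_ids <- records$aptamer_id[sig]
  list(records = records,
       up = records$aptamer_id[direction == "up_in_centenarians"],
       down = records$aptamer_id[direction == "down_in_centenarians"],
       mixed = records$aptamer_id[direction == "mixed"],
       n_aptamers = length(sig_ids),
       n_proteins = length(unique(records$gene_symbol[sig])),
       fdr = fdr)
}

#' Offspring versus control contrast
#'
#' Two-group covariate-adjusted test (sex, collection year) per aptamer on
#' the offspring and control samples only, with BH adjustment, plus the
#' nominal p < 0.05 list used by the delayed-aging pattern analysis.
#'
#' @inheritParams centenarian_signature
#' @param nominal_p nominal threshold for the delayed-aging candidate list.
#' @return list with `records` (effect = adjusted offspring-minus-control
#'   log difference), `significant` ids at q < `fdr` and `nominal` ids at
#'   p < `nominal_p`.
#' @export
offspring_control_contrast <- function(study, fdr = 0.01, nominal_p = 0.05,
                                       year_as_factor = FALSE) {
  keep <- study$samples$group %in% c("offspring", "control")
  if (sum(keep) == 0) stop2("no offspring/control samples")
  samples <- study$samples[keep, , drop = FALSE]
  ind <- factor(samples$group, levels = c("control", "offspring"))
  if (nlevels(droplevels(ind)) != 2) stop2("both groups must be present")
  covs <- diff_covariates(samples, year_as_factor)
  fit <- binary_t_matrix(log_expr(study)[keep, , drop = FALSE], ind, covs)
  q <- bh_adjust(fit$p)
  records <- data.frame(
    aptamer_id = study$aptamers$aptamer_id,
    gene_symbol = study$aptamers$gene_symbol,
    t = fit$t, p = fit$p, q = q,
    effect = fit$effect,           # offspring minus control, log scale
    effect_sign = ifelse(fit$effect >= 0, 1L, -1L),
    stringsAsFactors = FALSE
  )
  rownames(records) <- NULL
  list(records = records,
       significant = records$aptamer_id[q < fdr],
       nominal = records$aptamer_id[fit$p < nominal_p],
       fdr = fdr)
}

#' Dichotomize survival follow-up into short/long classes
#'
#' Centenarians are split at 2 years after the blood draw (died before 2
#' years = short; survival, or follow-up while alive, of 2 years or more =
#' long). Offspring and controls are split at 10 years: death within 10
#' years (inclusive) = short, survival beyond 10 years = long. Samples
#' alive with follow-up not yet past their cutoff are "unlabeled".
#'
#' @param samples study sample table with `survival_years` (years from draw
#'   to death or last contact; NA if unknown) and `dead` (logical).
#' @return data.frame `sample_id`, `group`, `label`, `cutoff_years`.
#' @export
label_survival <- function(samples) {
  if (!all(c("survival_years", "dead") %in% names(samples))) {
    stop2("samples table needs survival_years and dead columns")
  }
  yrs <- samples$survival_years
  if (any(yrs < 0, na.rm = TRUE)) stop2("negative survival time")
  cent <- samples$group == "centenarian"
  cutoff <- ifelse(cent, 2, 10)
  label <- rep("unlabeled", nrow(samples))
  known <- !is.na(yrs)
  # centenarians: boundary closed on long ("2 years or more")
  label[known & cent & samples$dead & yrs < 2] <- "short"
  label[known & cent & yrs >= 2] <- "long"
  # younger: death at exactly 10 years counts as short ("within 10 years")
  label[known & !cent & samples$dead & yrs <= 10] <- "short"
  label[known & !cent & yrs > 10] <- "long"
  data.frame(sample_id = samples$sample_id, group = samples$group,
             label = label, cutoff_years = cutoff, stringsAsFactors = FALSE)
}

#' Survival signature within a subgroup
#'
#' Per-aptamer covariate-adjusted test of log-RFU against the long/short
#' survival class. Centenarians adjust for sex and age at draw; the younger
#' subgroup additionally adjusts for participant type (offspring vs
#' control). Selection is at nominal p < `alpha` (BH q is reported
#' alongside); the fold change long-versus-short is the adjusted geometric
#' ratio exp(effect), so its direction always matches the effect sign.
#'
#' @param study a `cent_study`.
#' @param labeling output of [label_survival()].
#' @param subgroup `"centenarians"` or `"younger"` (offspring + controls).
#' @param alpha nominal selection threshold (default 0.005).
#' @return list with `records`, `selected` aptamer ids, the
#'   observed-over-expected selection ratio and class counts.
#' @export
survival_signature <- function(study, labeling,
                               subgroup = c("centenarians", "younger"),
                               alpha = 0.005) {
  subgroup <- match.arg(subgroup)
  want <- if (subgroup == "centenarians") "centenarian" else
    c("offspring", "control")
  lab <- labeling[labeling$group %in% want & labeling$label != "unlabeled", ]
  if (nrow(lab) == 0) stop2("no labeled samples in subgroup ", subgroup)
  keep <- match(lab$sample_id, study$samples$sample_id)
  samples <- study$samples[keep, , drop = FALSE]
  ind <- factor(lab$label, levels = c("short", "long"))
  if (any(table(ind) < 2)) stop2("need at least 2 labeled samples per class")
  covs <- data.frame(sex = factor(samples$sex),
                     age_at_draw = as.numeric(samples$age_at_draw))
  if (subgroup == "younger") {
    covs$participant_type <- factor(samples$group,
                                    levels = c("control", "offspring"))
  }
  fit <- binary_t_matrix(log_expr(study)[keep, , drop = FALSE], ind, covs)
  q <- bh_adjust(fit$p)
  records <- data.frame(
    aptamer_id = study$aptamers$aptamer_id,
    gene_symbol = study$aptamers$gene_symbol,
    effect = fit$effect,                 # long minus short, log scale
    t = fit$t, p = fit$p, q = q,
    fc_long_vs_short = exp(fit$effect),
    stringsAsFactors = FALSE
  )
  rownames(records) <- NULL
  sel <- records$aptamer_id[fit$p < alpha]
  list(records = records, selected = sel, alpha = alpha,
       subgroup = subgroup,
       expected_ratio = expected_count_ratio(length(sel), nrow(records),
                                             alpha),
       n_short = sum(ind == "short"), n_long = sum(ind == "long"))
}

#' Observed-over-expected selection ratio
#'
#' Ratio of the number of aptamers selected at nominal level `alpha` to the
#' m * alpha expected by chance; a ratio of 1.5 is a 50 percent excess.
#'
#' @param n_selected selected count; @param m number of tests;
#' @param alpha nominal threshold.
#' @export
expected_count_ratio <- function(n_selected, m, alpha) {
  if (m <= 0) stop2("m must be positive")
  n_selected / (m * alpha)
}

#' Sign-quadrant classification of two signed signatures
#'
#' Assigns every aptamer shared by two signed-effect vectors to one of the
#' four sign quadrants, used for the age-by-survival pattern (e.g. proteins
#' up in centenarians but down with longer survival) and the delayed-aging
#' pattern in offspring. Zero effects go to a separate "zero" bucket.
#'
#' @param a,b named numeric vectors of signed effects.
#' @return list with `counts` (pp, pn, np, nn, zero) and the per-aptamer
#'   `assignment` data.frame.
#' @export
direction_pattern <- function(a, b) {
  keys <- intersect(names(a), names(b))
  sa <- sign(a[keys]); sb <- sign(b[keys])
  quadrant <- rep("zero", length(keys))
  quadrant[sa > 0 & sb > 0] <- "pp"
  quadrant[sa > 0 & sb < 0] <- "pn"
  quadrant[sa < 0 & sb > 0] <- "np"
  quadrant[sa < 0 & sb < 0] <- "nn"
  counts <- vapply(c("pp", "pn", "np", "nn", "zero"),
                   function(qd) sum(quadrant == qd), integer(1))
  list(counts = counts,
       assignment = data.frame(aptamer_id = keys, a = unname(a[keys]),
                               b = unname(b[keys]), quadrant = quadrant,
                               stringsAsFactors = FALSE))
}
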