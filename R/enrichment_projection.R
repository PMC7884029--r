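# Gene-set over-representation and per-sample pathway projection scores.

#' Fisher-exact over-representation of a protein set
#'
#' For each gene set in the collection, intersects the set with the
#' universe, builds the (in target) x (in set) 2x2 table over the universe
#' and applies the two-sided [fisher_exact_2x2()], with BH across the
#' collection. Membership is at gene-symbol level so multiple aptamers per
#' protein count once.
#'
#' @param target character vector of gene symbols (restricted to the
#'   universe before testing).
#' @param collection named list of gene-symbol sets (`gene_set_collection`).
#' @param universe character vector of all platform gene symbols.
#' @return data.frame with one row per set: overlap, set size in universe,
#'   target size, universe size, odds ratio, p, q.
#' @export
enrich <- function(target, collection, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stop2("empty universe")
  target <- unique(intersect(target, universe))
  rows <- lapply(names(collection), function(nm) {
    s <- unique(intersect(collection[[nm]], universe))
    a <- length(intersect(target, s))
    b <- length(target) - a
    c_ <- length(s) - a
    d <- length(universe) - length(target) - c_
    ft <- fisher_exact_2x2(matrix(c(a, b, c_, d), 2, 2, byrow = TRUE))
    data.frame(set_name = nm, overlap = a, set_size_in_universe = length(s),
               target_size = length(target),
               universe_size = length(universe),
               odds_ratio = ft$odds_ratio, p = ft$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(set_name = character(0), overlap = integer(0),
                      set_size_in_universe = integer(0),
                      target_size = integer(0), universe_size = integer(0),
                      odds_ratio = numeric(0), p = numeric(0),
                      q = numeric(0))
    return(out)
  }
  out$q <- bh_adjust(out$p)
  rownames(out) <- NULL
  out
}

#' Per-sample pathway projection scores
#'
#' Each aptamer's log-RFU is z-standardized across samples; a pathway's
#' score for a sample is the mean z over its member aptamers (matched by
#' gene symbol). Pathways with fewer than `min_members` platform members
#' are dropped with a warning. Scores are invariant to per-aptamer affine
#' rescaling of the input.
#'
#' @param study a `cent_study`.
#' @param collection named list of gene-symbol sets.
#' @param min_members minimum platform members per pathway (default 5).
#' @return list with `scores` (samples x pathways matrix) and
#'   `n_members` per pathway.
#' @export
project_pathways <- function(study, collection, min_members = 5) {
  if (length(collection) == 0) stop2("empty gene-set collection")
  Z <- scale(log_expr(study))
  Z[, attr(Z, "scaled:scale") == 0] <- 0     # flat aptamers carry no signal
  sym <- study$aptamers$gene_symbol
  scores <- list()
  n_members <- integer(0)
  for (nm in names(collection)) {
    members <- which(sym %in% collection[[nm]])
    if (length(members) < min_members) {
      warning("dropping pathway '", nm, "': ", length(members),
              " platform member(s) < ", min_members)
      next
    }
    scores[[nm]] <- rowMeans(Z[, members, drop = FALSE])
    n_members[nm] <- length(members)
  }
  if (length(scores) == 0) stop2("no pathway passed the membership filter")
  S <- do.call(cbind, scores)
  rownames(S) <- rownames(study$expression)
  list(scores = S, n_members = n_members)
}

#' Differential testing of pathway projection scores
#'
#' Applies the same covariate-adjusted models used at the protein level to
#' each pathway score column: the three-group ANOVA F-test (sex +
#' collection year) or the survival-class t-test, with BH across pathways.
#'
#' @param projection output of [project_pathways()].
#' @param study a `cent_study`.
#' @param design `"three_group"` or `"survival"`.
#' @param labeling survival labeling (required for `design = "survival"`).
#' @param subgroup survival subgroup, as in [survival_signature()].
#' @param fdr pathway FDR threshold (default 0.05).
#' @return data.frame per pathway: statistic, p, q, direction (sign of the
#'   centenarian, or long-survival, adjusted difference), significance.
#' @export
pathway_differential <- function(projection, study,
                                 design = c("three_group", "survival"),
                                 labeling = NULL,
                                 subgroup = "centenarians", fdr = 0.05) {
  design <- match.arg(design)
  S <- projection$scores
  if (design == "three_group") {
    keep <- match(rownames(S), study$samples$sample_id)
    g <- as_group_factor(study$samples$group[keep])
    covs <- diff_covariates(study$samples[keep, , drop = FALSE])
    fit <- anova_f_matrix(S, g, covs)
    gm <- fit$group_means
    dir_eff <- gm["centenarian", ] -
      (gm["offspring", ] + gm["control", ]) / 2
    out <- data.frame(pathway = colnames(S), statistic = fit$F,
                      p = fit$p, q = bh_adjust(fit$p),
                      direction = ifelse(dir_eff >= 0, 1L, -1L),
                      stringsAsFactors = FALSE)
  } else {
    if (is.null(labeling)) stop2("survival design needs a labeling")
    want <- if (subgroup == "centenarians") "centenarian" else
      c("offspring", "control")
    lab <- labeling[labeling$group %in% want & labeling$label != "unlabeled", ]
    lab <- lab[lab$sample_id %in% rownames(S), , drop = FALSE]
    keep <- match(lab$sample_id, study$samples$sample_id)
    samples <- study$samples[keep, , drop = FALSE]
    ind <- factor(lab$label, levels = c("short", "long"))
    covs <- data.frame(sex = factor(samples$sex),
                       age_at_draw = as.numeric(samples$age_at_draw))
    if (subgroup != "centenarians") {
      covs$participant_type <- factor(samples$group,
                                      levels = c("control", "offspring"))
    }
    fit <- binary_t_matrix(S[lab$sample_id, , drop = FALSE], ind, covs)
    out <- data.frame(pathway = colnames(S), statistic = fit$t,
                      p = fit$p, q = bh_adjust(fit$p),
                      direction = ifelse(fit$effect >= 0, 1L, -1L),
                      stringsAsFactors = FALSE)
  }
  out$significant <- out$q < fdr
  rownames(out) <- NULL
  out
}
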