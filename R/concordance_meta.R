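# Cross-study significance-tier classification, concordance testing,
# derived signatures, Stouffer meta-analysis and replication union.

#' Three-way significance tier
#'
#' significant: BH q below `fdr`; not_significant: p above `p_ns`;
#' ambiguous otherwise. Every (p, q) pair maps to exactly one tier.
#'
#' @param p,q nominal and BH-adjusted p-values (vectorized).
#' @param fdr significance threshold on q (default 0.01).
#' @param p_ns not-significant threshold on p (default 0.2).
#' @return character vector of tiers.
#' @export
assign_tier <- function(p, q, fdr = 0.01, p_ns = 0.2) {
  if (any(p < 0 | p > 1 | q < 0 | q > 1, na.rm = TRUE)) {
    stop2("p and q must lie in [0, 1]")
  }
  ifelse(q < fdr, "significant",
         ifelse(p > p_ns, "not_significant", "ambiguous"))
}

TIER_LEVELS <- c("significant", "ambiguous", "not_significant")

# Normalize internal records (centenarian_signature()$records or any
# data.frame with aptamer_id, p, effect_sign) and an external summary table
# to the shared key set, re-running BH within the intersection.
align_studies <- function(internal, external, fdr = 0.01, p_ns = 0.2) {
  if (is.list(internal) && !is.data.frame(internal)) {
    internal <- internal$records
  }
  key_int <- internal$aptamer_id
  key_ext <- external$aptamer_id
  shared <- intersect(key_int, key_ext)
  if (length(shared) == 0) stop2("empty platform intersection")
  i <- match(shared, key_int)
  e <- match(shared, key_ext)
  p_int <- internal$p[i] %||% internal$p_value[i]
  p_ext <- external$p_value[e]
  # BH is recomputed within the compared universe so tiers are well defined
  q_int <- bh_adjust(p_int)
  q_ext <- bh_adjust(p_ext)
  data.frame(aptamer_id = shared,
             p_internal = p_int, q_internal = q_int,
             sign_internal = internal$effect_sign[i],
             tier_internal = assign_tier(p_int, q_int, fdr, p_ns),
             p_external = p_ext, q_external = q_ext,
             sign_external = external$effect_sign[e],
             tier_external = assign_tier(p_ext, q_ext, fdr, p_ns),
             stringsAsFactors = FALSE)
}

#' Cross-classification of significance tiers between two studies
#'
#' Restricts both studies to their platform intersection, re-runs BH within
#' the intersection on each side, assigns tiers, and tallies the 3x3
#' internal-by-external table whose cells sum to the intersection size.
#'
#' @param internal differential records (or the list returned by
#'   [centenarian_signature()]) with `aptamer_id`, `p`, `effect_sign`.
#' @param external external summary table with `aptamer_id`, `p_value`,
#'   `effect_sign`.
#' @param fdr,p_ns tier thresholds (see [assign_tier()]).
#' @return list with `table` (3x3), `data` (per-aptamer tiers and signs on
#'   the intersection) and `n_overlap`.
#' @export
cross_classify <- function(internal, external, fdr = 0.01, p_ns = 0.2) {
  dat <- align_studies(internal, external, fdr, p_ns)
  tab <- table(factor(dat$tier_internal, levels = TIER_LEVELS),
               factor(dat$tier_external, levels = TIER_LEVELS),
               dnn = c("internal", "external"))
  list(table = tab, data = dat, n_overlap = nrow(dat))
}

#' Fisher test of sign concordance by signature membership
#'
#' Tests whether aptamers inside a signature have concordant cross-study
#' effect directions more often than those outside, via the two-sided
#' Fisher exact test on the membership-by-concordance 2x2 table.
#'
#' @param membership logical vector: in the signature.
#' @param concordant logical vector (same keys): effect signs agree.
#' @return list with `p_value`, `odds_ratio`, the 2x2 `table` and the
#'   per-stratum concordance `rates`.
#' @export
sign_concordance_test <- function(membership, concordant) {
  if (length(membership) != length(concordant)) {
    stop2("membership and concordant must be aligned")
  }
  tab <- matrix(c(sum(membership & concordant), sum(membership & !concordant),
                  sum(!membership & concordant), sum(!membership & !concordant)),
                2, 2, byrow = TRUE,
                dimnames = list(membership = c("in", "out"),
                                concordant = c("yes", "no")))
  ft <- fisher_exact_2x2(tab)
  list(p_value = ft$p_value, odds_ratio = ft$odds_ratio, table = tab,
       rates = c(members = tab[1, 1] / max(sum(tab[1, ]), 1),
                 non_members = tab[2, 1] / max(sum(tab[2, ]), 1)))
}

#' Derive replicated / extreme-old-age / immune-senescence signatures
#'
#' From tiered internal and external results on the platform intersection:
#' `replicated` = significant in both with concordant sign;
#' `extreme_old_age` = internally significant but clearly flat with age
#' externally (p > 0.2); `immune_senescence` = externally age-associated
#' but flat internally. Jointly significant discordant-sign aptamers are
#' reported separately. The three sets are pairwise disjoint.
#'
#' @param crossdata the `data` element of [cross_classify()].
#' @return list of aptamer-id sets.
#' @export
derive_signatures <- function(crossdata) {
  d <- crossdata
  int_sig <- d$tier_internal == "significant"
  ext_sig <- d$tier_external == "significant"
  int_ns <- d$tier_internal == "not_significant"
  ext_ns <- d$tier_external == "not_significant"
  same <- d$sign_internal == d$sign_external
  list(replicated = d$aptamer_id[int_sig & ext_sig & same],
       extreme_old_age = d$aptamer_id[int_sig & ext_ns],
       immune_senescence = d$aptamer_id[ext_sig & int_ns],
       discordant = d$aptamer_id[int_sig & ext_sig & !same])
}

#' Stouffer meta-analysis of two studies' summary results
#'
#' Restricts to aptamers with p below `p_max` in both studies, converts
#' each study to a signed z (z = sign * qnorm(1 - p/2), p clipped at
#' 1e-300), combines with [stouffer_meta()] weighted by the square root of
#' each study's sample size, and applies BH across the restricted set.
#'
#' @param internal differential records with `aptamer_id`, `p`,
#'   `effect_sign`; @param external external summary table.
#' @param n_internal internal study sample size.
#' @param n_external external sample size; defaults to the external
#'   table's `n_samples` column.
#' @param p_max restriction threshold (default 0.2).
#' @param fdr significance threshold on the meta q (default 0.01).
#' @return list with `records` (z per study, meta z, p, q),
#'   `significant` ids, and the per-study significant counts on the same
#'   restricted universe for comparison.
#' @export
meta_analyze <- function(internal, external, n_internal,
                         n_external = NULL, p_max = 0.2, fdr = 0.01) {
  if (is.list(internal) && !is.data.frame(internal)) {
    internal <- internal$records
  }
  if (is.null(n_external)) {
    if (!"n_samples" %in% names(external)) stop2("missing external sample size")
    n_external <- external$n_samples[1]
  }
  if (is.null(n_internal) || is.na(n_internal)) stop2("missing internal sample size")
  dat <- align_studies(internal, external)
  dat <- dat[dat$p_internal < p_max & dat$p_external < p_max, , drop = FALSE]
  if (nrow(dat) == 0) {
    return(list(records = dat, significant = character(0),
                n_restricted = 0))
  }
  to_z <- function(p, s) s * stats::qnorm(1 - pmax(p, 1e-300) / 2)
  z_int <- to_z(dat$p_internal, dat$sign_internal)
  z_ext <- to_z(dat$p_external, dat$sign_external)
  w <- sqrt(c(n_internal, n_external))
  z_meta <- (w[1] * z_int + w[2] * z_ext) / sqrt(sum(w^2))
  p_meta <- 2 * stats::pnorm(-abs(z_meta))
  q_meta <- bh_adjust(p_meta)
  records <- data.frame(aptamer_id = dat$aptamer_id,
                        z_internal = z_int, z_external = z_ext,
                        z_meta = z_meta, p = p_meta, q = q_meta,
                        stringsAsFactors = FALSE)
  list(records = records,
       significant = records$aptamer_id[q_meta < fdr],
       n_restricted = nrow(records),
       n_single_internal = sum(bh_adjust(dat$p_internal) < fdr),
       n_single_external = sum(bh_adjust(dat$p_external) < fdr))
}

#' Union of per-study replicated sets with provenance
#'
#' @param sets named list of aptamer-id vectors, one per replication study.
#' @param aptamers optional aptamer table for the unique-protein count.
#' @return list with `union` ids, a `provenance` logical matrix
#'   (aptamer x study), and aptamer / unique-protein counts.
#' @export
replication_union <- function(sets, aptamers = NULL) {
  ids <- sort(unique(unlist(sets)))
  prov <- vapply(sets, function(s) ids %in% s, logical(length(ids)))
  if (length(ids) == 1) prov <- matrix(prov, nrow = 1,
                                       dimnames = list(ids, names(sets)))
  else rownames(prov) <- ids
  n_prot <- if (!is.null(aptamers)) {
    length(unique(aptamers$gene_symbol[aptamers$aptamer_id %in% ids]))
  } else NA_integer_
  list(union = ids, provenance = prov, n_aptamers = length(ids),
       n_proteins = n_prot)
}

#' Consistency filter for an external study against a reference
#'
#' Mirrors the multi-study replication cleanup: drops aptamers whose
#' external effect sign disagrees with a reference study's sign, and drops
#' aptamers not significantly age-associated in the external study itself
#' (BH within the external table at `fdr`).
#'
#' @param external external summary table (`aptamer_id`, `effect_sign`,
#'   `p_value`).
#' @param reference reference table with `aptamer_id`, `effect_sign`.
#' @param fdr external significance threshold (default 0.01).
#' @return the surviving subset of `external`, with a `q_value` column.
#' @export
filter_interval_style <- function(external, reference, fdr = 0.01) {
  external$q_value <- bh_adjust(external$p_value)
  ref_sign <- reference$effect_sign[match(external$aptamer_id,
                                          reference$aptamer_id)]
  keep <- external$q_value < fdr &
    (is.na(ref_sign) | external$effect_sign == ref_sign)
  out <- external[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
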