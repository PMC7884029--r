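# Within-group weighted co-expression modules: correlation -> soft
# threshold -> topological overlap -> average-linkage clustering with a
# flat height cut and a size filter, then eigengenes, group-difference
# scores and the two-layer cross-group module graph.

#' Aptamer-by-aptamer Pearson correlation within a sample subset
#'
#' @param study a `cent_study`.
#' @param sample_ids samples defining the subset (at least 10).
#' @return symmetric correlation matrix on log-RFU; zero-variance aptamers
#'   get correlation 0 (with a warning), diagonal 1.
#' @export
correlation_matrix <- function(study, sample_ids) {
  if (length(sample_ids) < 10) stop2("need at least 10 samples")
  L <- log_expr(study)[sample_ids, , drop = FALSE]
  sds <- apply(L, 2, stats::sd)
  flat <- sds == 0
  if (any(flat)) {
    warning(sum(flat), " zero-variance aptamer(s); correlations set to 0")
  }
  r <- suppressWarnings(stats::cor(L))
  r[flat, ] <- 0
  r[, flat] <- 0
  diag(r) <- 1
  r
}

#' Select the soft-threshold power by scale-free fit
#'
#' Builds unsigned adjacency a = |r|^beta for each candidate power and
#' picks the smallest beta whose connectivity distribution achieves a
#' scale-free model fit R^2 of at least `target_fit` (with negative
#' slope); if none qualifies, the beta with maximal R^2 is used.
#'
#' @param corr correlation matrix.
#' @param powers candidate integer powers (default 1:12).
#' @param target_fit R^2 target (default 0.8).
#' @param n_breaks connectivity histogram bins for the fit.
#' @return list with `power`, and `fit_table` (power, r_squared, slope,
#'   mean adjacency).
#' @export
soft_threshold_select <- function(corr, powers = 1:12, target_fit = 0.8,
                                  n_breaks = 10) {
  a0 <- abs(corr)
  diag(a0) <- 0
  fit_one <- function(beta) {
    A <- a0^beta
    k <- rowSums(A)
    if (stats::sd(k) == 0) return(c(r2 = 0, slope = 0, mean_adj = mean(A)))
    cuts <- cut(k, breaks = n_breaks)
    dk <- tapply(k, cuts, mean)
    pk <- tabulate(cuts, nbins = nlevels(cuts)) / length(k)
    ok <- !is.na(dk) & pk > 0 & dk > 0
    if (sum(ok) < 3) return(c(r2 = 0, slope = 0, mean_adj = mean(A)))
    fit <- stats::lm(log10(pk[ok]) ~ log10(dk[ok]))
    c(r2 = summary(fit)$r.squared * sign(-stats::coef(fit)[2]),
      slope = unname(stats::coef(fit)[2]), mean_adj = mean(A))
  }
  tab <- t(vapply(powers, fit_one, numeric(3)))
  fit_table <- data.frame(power = powers, r_squared = tab[, 1],
                          slope = tab[, 2], mean_adjacency = tab[, 3])
  r2 <- fit_table$r_squared
  hit <- which(r2 >= target_fit)
  # plateau rule: once the fit gain per step flattens (< 0.05) at a
  # reasonable fit (>= 0.5), raising the power further only erodes weak
  # within-module adjacencies without improving scale-freeness
  plateau <- which(diff(r2) < 0.05 & r2[-1] >= 0.5)
  cand <- c(if (length(hit) > 0) hit[1],
            if (length(plateau) > 0) plateau[1] + 1)
  power <- if (length(cand) > 0) powers[min(cand)] else
    powers[which.max(r2)]
  list(power = power, fit_table = fit_table)
}

#' Topological overlap matrix
#'
#' TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij) with
#' k = row sums of the (zero-diagonal) adjacency; TOM_ii = 1. Neighborhood
#' sharing stabilizes module detection against single noisy correlations.
#'
#' @param adjacency symmetric matrix with entries in \[0, 1\].
#' @return TOM similarity matrix.
#' @export
topological_overlap <- function(adjacency) {
  if (!isSymmetric(unname(adjacency), tol = 1e-10)) {
    stop2("adjacency must be symmetric")
  }
  A <- adjacency
  diag(A) <- 0
  if (any(A < 0 | A > 1)) stop2("adjacency entries must lie in [0, 1]")
  L <- A %*% A
  k <- rowSums(A)
  denom <- outer(k, k, pmin) + 1 - A
  tom <- (L + A) / denom
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

#' Detect co-expression modules from a TOM
#'
#' Average-linkage hierarchical clustering on dissimilarity 1 - TOM, flat
#' cut at `cut_height` (default: 0.995 times the largest merge height),
#' with clusters smaller than `min_module_size` dissolved into the null
#' module and a background filter that drops cut clusters no tighter than
#' the matrix-wide similarity level. Modules are labeled M1, M2, ... by decreasing size. Detection
#' is deterministic given the matrix.
#'
#' @param tom TOM similarity matrix (named dims = aptamer ids).
#' @param min_module_size minimum module size (default 20).
#' @param cut_height flat cut height on 1 - TOM; NULL for the quantile rule.
#' @return list with `modules` (named list of aptamer-id vectors),
#'   `null_module` ids, `labels` (named vector, "null" for unassigned) and
#'   the `cut_height` used.
#' @export
detect_modules <- function(tom, min_module_size = 20, cut_height = NULL) {
  ids <- colnames(tom) %||% as.character(seq_len(ncol(tom)))
  d <- 1 - tom
  off <- d[upper.tri(d)]
  if (length(unique(round(off, 12))) <= 1) {
    labels <- stats::setNames(rep("null", length(ids)), ids)
    return(list(modules = list(), null_module = ids, labels = labels,
                cut_height = NA_real_))
  }
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  if (is.null(cut_height)) {
    # the unstructured background coalesces in a narrow band just below the
    # top of the dendrogram; cutting slightly under the final merge leaves
    # genuinely tight clusters intact while the background disperses
    cut_height <- 0.995 * max(hc$height)
  }
  cl <- stats::cutree(hc, h = cut_height)
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= min_module_size]
  # the cut's largest cluster is typically the unstructured background;
  # a cluster counts as a module only if clearly tighter than background
  labels <- rep("null", length(ids))
  names(labels) <- ids
  kept <- list()
  for (k in keep) {
    members <- ids[cl == as.integer(k)]
    kept[[length(kept) + 1]] <- members
  }
  if (length(kept) > 0) {
    # drop the background cluster: the one with lowest internal similarity
    med_sim <- vapply(kept, function(mem) {
      sub <- tom[mem, mem]
      stats::median(sub[upper.tri(sub)])
    }, numeric(1))
    sim_off <- tom[upper.tri(tom)]
    bg_sim <- stats::median(sim_off) + stats::mad(sim_off)
    is_module <- med_sim > bg_sim
    kept <- kept[is_module]
  }
  if (length(kept) > 0) {
    ord <- order(vapply(kept, length, integer(1)), decreasing = TRUE)
    kept <- kept[ord]
    names(kept) <- paste0("M", seq_along(kept))
    for (nm in names(kept)) labels[kept[[nm]]] <- nm
  }
  list(modules = kept, null_module = ids[labels == "null"], labels = labels,
       cut_height = cut_height)
}

#' Module eigengene
#'
#' First principal component of the per-aptamer z-standardized submatrix
#' over the given samples, scaled to unit variance and sign-oriented to
#' correlate positively with the module's average z profile.
#'
#' @param study a `cent_study`.
#' @param members aptamer ids of the module (non-empty).
#' @param sample_ids samples on which the eigengene is computed.
#' @return named numeric vector, one value per sample, unit variance.
#' @export
module_eigengene <- function(study, members, sample_ids) {
  if (length(members) == 0) stop2("empty module")
  if (length(sample_ids) < 2) stop2("need at least 2 samples")
  Z <- scale(log_expr(study)[sample_ids, members, drop = FALSE])
  Z[, attr(Z, "scaled:scale") == 0] <- 0
  sv <- svd(Z, nu = 1, nv = 0)
  e <- sv$u[, 1]
  e <- e / stats::sd(e)
  avg <- rowMeans(Z)
  if (sum(e * avg) < 0) e <- -e
  stats::setNames(e, sample_ids)
}

#' Average standardized expression difference of a module between groups
#'
#' Aptamers are z-standardized over all samples of the study; the score is
#' the mean, over module members, of (mean z in the focal group - mean z in
#' the other group). Swapping focal and other groups negates the value.
#'
#' @param study a `cent_study`.
#' @param members module aptamer ids.
#' @param focal_samples,other_samples sample-id vectors of the two groups.
#' @return scalar average standardized difference.
#' @export
module_group_difference <- function(study, members, focal_samples,
                                    other_samples) {
  if (length(members) == 0) stop2("empty module")
  if (length(focal_samples) == 0 || length(other_samples) == 0) {
    stop2("both groups must be present")
  }
  Z <- scale(log_expr(study)[, members, drop = FALSE])
  Z[, attr(Z, "scaled:scale") == 0] <- 0
  mean(colMeans(Z[focal_samples, , drop = FALSE]) -
         colMeans(Z[other_samples, , drop = FALSE]))
}

#' Full within-group module analysis
#'
#' Runs correlation -> soft-threshold selection -> TOM -> module detection
#' on the focal group's samples, then computes each module's eigengene (on
#' the focal samples) and average standardized difference versus the other
#' group.
#'
#' @param study a `cent_study`.
#' @param focal_groups group label(s) defining the focal sample set (e.g.
#'   `"centenarian"`, or `c("offspring", "control")`).
#' @param label display label for the module set.
#' @param min_module_size,cut_height passed to [detect_modules()].
#' @param powers,target_fit passed to [soft_threshold_select()].
#' @return a `module_set`: group label, modules, null module, eigengene
#'   matrix (focal samples x modules), `avg_std_diff` per module, chosen
#'   power and cut height.
#' @export
build_module_set <- function(study, focal_groups, label = focal_groups[1],
                             min_module_size = 20, cut_height = NULL,
                             powers = 1:12, target_fit = 0.8) {
  focal <- study$samples$sample_id[study$samples$group %in% focal_groups]
  other <- setdiff(study$samples$sample_id, focal)
  r <- correlation_matrix(study, focal)
  st <- soft_threshold_select(r, powers, target_fit)
  A <- abs(r)^st$power
  diag(A) <- 0
  tom <- topological_overlap(A)
  det <- detect_modules(tom, min_module_size, cut_height)
  eig <- NULL
  asd <- numeric(0)
  if (length(det$modules) > 0) {
    eig <- vapply(det$modules, function(mem) {
      module_eigengene(study, mem, focal)
    }, numeric(length(focal)))
    rownames(eig) <- focal
    asd <- vapply(det$modules, function(mem) {
      module_group_difference(study, mem, focal, other)
    }, numeric(1))
  }
  structure(list(group = label, modules = det$modules,
                 null_module = det$null_module, labels = det$labels,
                 eigengenes = eig, avg_std_diff = asd,
                 power = st$power, cut_height = det$cut_height,
                 universe = study$aptamers$aptamer_id),
            class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  cat("module_set [", x$group, "]: ", length(x$modules), " modules, ",
      length(x$null_module), " unassigned aptamers\n", sep = "")
  invisible(x)
}

#' Two-layer cross-group module graph
#'
#' Nodes are the (non-null) modules of both groups, annotated with size
#' and average standardized difference. Within-group edges connect module
#' pairs with absolute eigengene correlation above `me_cor_threshold`;
#' cross-group edges connect modules whose memberships overlap with
#' Jaccard index above `jaccard_threshold`.
#'
#' @param modules_a,modules_b `module_set` objects on the same aptamer
#'   universe.
#' @param me_cor_threshold eigengene correlation threshold (default 0.8).
#' @param jaccard_threshold Jaccard overlap threshold (default 0.10).
#' @return list with `nodes`, `within_edges`, `cross_edges` data.frames.
#' @export
build_module_graph <- function(modules_a, modules_b,
                               me_cor_threshold = 0.8,
                               jaccard_threshold = 0.10) {
  if (!setequal(modules_a$universe, modules_b$universe)) {
    stop2("module sets live on different aptamer universes")
  }
  node_df <- function(ms) {
    if (length(ms$modules) == 0) {
      return(data.frame(group = character(0), module = character(0),
                        size = integer(0), avg_std_diff = numeric(0)))
    }
    data.frame(group = ms$group, module = names(ms$modules),
               size = vapply(ms$modules, length, integer(1)),
               avg_std_diff = unname(ms$avg_std_diff),
               stringsAsFactors = FALSE)
  }
  nodes <- rbind(node_df(modules_a), node_df(modules_b))
  rownames(nodes) <- NULL

  within_edges <- function(ms) {
    out <- data.frame(group = character(0), module_1 = character(0),
                      module_2 = character(0), eigengene_cor = numeric(0))
    if (length(ms$modules) < 2) return(out)
    cm <- stats::cor(ms$eigengenes)
    nm <- colnames(cm)
    for (i in seq_len(ncol(cm) - 1)) {
      for (j in (i + 1):ncol(cm)) {
        if (abs(cm[i, j]) > me_cor_threshold) {
          out <- rbind(out, data.frame(group = ms$group, module_1 = nm[i],
                                       module_2 = nm[j],
                                       eigengene_cor = cm[i, j]))
        }
      }
    }
    out
  }
  we <- rbind(within_edges(modules_a), within_edges(modules_b))
  rownames(we) <- NULL

  ce <- data.frame(module_a = character(0), module_b = character(0),
                   jaccard = numeric(0))
  for (na_ in names(modules_a$modules)) {
    for (nb in names(modules_b$modules)) {
      A <- modules_a$modules[[na_]]
      B <- modules_b$modules[[nb]]
      jac <- length(intersect(A, B)) / length(union(A, B))
      if (jac > jaccard_threshold) {
        ce <- rbind(ce, data.frame(module_a = na_, module_b = nb,
                                   jaccard = jac))
      }
    }
  }
  rownames(ce) <- NULL
  list(nodes = nodes, within_edges = we, cross_edges = ce,
       me_cor_threshold = me_cor_threshold,
       jaccard_threshold = jaccard_threshold)
}
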