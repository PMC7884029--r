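# End-to-end orchestration: QC -> differential -> survival -> concordance
# -> enrichment -> projection -> network, with a machine-readable report.

#' Flag and remove outlier samples by mean inter-sample correlation
#'
#' Computes each sample's mean Pearson correlation (log-RFU) to all other
#' samples; samples whose robust z-score (median/MAD) falls below
#' `-z_cut` are removed; one further pass is run on the reduced data.
#' Aborts if more than 10 percent of samples would be removed.
#'
#' @param study a `cent_study` with at least 10 samples.
#' @param z_cut robust z threshold (default 5).
#' @return list with the filtered `study` and `removed` sample ids.
#' @export
qc_outlier_samples <- function(study, z_cut = 5) {
  if (nrow(study$expression) < 10) stop2("need at least 10 samples for QC")
  removed <- character(0)
  current <- study
  for (pass in 1:2) {
    L <- log_expr(current)
    cc <- stats::cor(t(L))
    diag(cc) <- NA
    mean_cor <- rowMeans(cc, na.rm = TRUE)
    med <- stats::median(mean_cor)
    madv <- stats::mad(mean_cor)
    if (madv == 0) break
    z <- (mean_cor - med) / madv
    bad <- names(z)[z < -z_cut]
    if (length(bad) == 0) break
    removed <- c(removed, bad)
    if (length(removed) > 0.1 * nrow(study$expression)) {
      stop2("QC would remove more than 10% of samples (",
            length(removed), " of ", nrow(study$expression),
            "); check the input data")
    }
    keep <- setdiff(current$samples$sample_id, bad)
    current <- new_study(current$expression[keep, , drop = FALSE],
                         current$samples[current$samples$sample_id %in% keep, ],
                         current$aptamers)
  }
  list(study = current, removed = removed)
}

#' Run configuration for the full pipeline
#'
#' @param sim simulation configuration ([sim_config()]) for synthetic runs,
#'   or NULL when input paths are given.
#' @param expression_path,samples_path,aptamers_path input TSVs (ignored
#'   when `sim` is given).
#' @param gmt_path optional GMT of gene sets; for simulated runs a fixture
#'   collection is generated from the truth when omitted.
#' @param fdr,p_ns,survival_alpha,pathway_fdr,me_cor,jaccard,min_module_size
#'   analysis thresholds.
#' @param seed integer seed for the run.
#' @param out_dir optional output directory for result tables.
#' @return a `run_config` list.
#' @export
run_config <- function(sim = NULL, expression_path = NULL,
                       samples_path = NULL, aptamers_path = NULL,
                       gmt_path = NULL,
                       fdr = 0.01, p_ns = 0.2, survival_alpha = 0.005,
                       pathway_fdr = 0.05, me_cor = 0.8, jaccard = 0.10,
                       min_module_size = 20, seed = 1L, out_dir = NULL) {
  if (is.null(sim) && is.null(expression_path)) {
    stop2("either a simulation config or input paths must be given")
  }
  stopifnot(fdr > 0, fdr < 1, p_ns > 0, p_ns < 1,
            survival_alpha > 0, survival_alpha < 1,
            pathway_fdr > 0, pathway_fdr < 1,
            me_cor > 0, me_cor <= 1, jaccard >= 0, jaccard <= 1,
            min_module_size >= 1)
  structure(list(sim = sim, expression_path = expression_path,
                 samples_path = samples_path, aptamers_path = aptamers_path,
                 gmt_path = gmt_path, fdr = fdr, p_ns = p_ns,
                 survival_alpha = survival_alpha, pathway_fdr = pathway_fdr,
                 me_cor = me_cor, jaccard = jaccard,
                 min_module_size = min_module_size, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes QC, the centenarian differential signature, the
#' offspring-versus-control contrast, both survival signatures, the
#' cross-study concordance + meta-analysis (for simulated runs, against a
#' simulated external study), gene-set enrichment of the signature,
#' pathway projection with group differential testing, and the two-group
#' co-expression module network. Regenerating with the same config and
#' seed reproduces identical tables.
#'
#' @param config a [run_config()].
#' @param network whether to run the module-network stage (the slowest).
#' @return a report bundle: per-stage result objects plus `meta` (seed,
#'   thresholds, QC removals, stage flags).
#' @export
run_full_analysis <- function(config, network = TRUE) {
  stages <- character(0)
  fail <- function(stage, e) {
    stop2("stage '", stage, "' failed: ", conditionMessage(e))
  }
  truth <- NULL
  if (!is.null(config$sim)) {
    sim <- tryCatch(simulate_cohort(config$sim),
                    error = function(e) fail("simulate", e))
    study <- sim$study
    truth <- sim$truth
  } else {
    study <- tryCatch(load_study(config$expression_path,
                                 config$samples_path,
                                 config$aptamers_path),
                      error = function(e) fail("load", e))
  }

  qc <- tryCatch(qc_outlier_samples(study),
                 error = function(e) fail("qc", e))
  study <- qc$study
  stages <- c(stages, "qc")

  diff <- tryCatch(centenarian_signature(study, fdr = config$fdr),
                   error = function(e) fail("differential", e))
  offc <- tryCatch(offspring_control_contrast(study, fdr = config$fdr),
                   error = function(e) fail("offspring_contrast", e))
  stages <- c(stages, "differential")

  surv_cent <- surv_young <- labeling <- NULL
  if (all(c("survival_years", "dead") %in% names(study$samples)) &&
      any(!is.na(study$samples$survival_years))) {
    labeling <- label_survival(study$samples)
    surv_cent <- tryCatch(
      survival_signature(study, labeling, "centenarians",
                         alpha = config$survival_alpha),
      error = function(e) NULL)
    surv_young <- tryCatch(
      survival_signature(study, labeling, "younger",
                         alpha = config$survival_alpha),
      error = function(e) NULL)
    stages <- c(stages, "survival")
  }

  concordance <- meta <- external <- NULL
  if (!is.null(truth)) {
    external <- simulate_external_study(truth, n_samples = 240,
                                        seed = config$seed + 1000L)
    concordance <- cross_classify(diff, external, fdr = config$fdr,
                                  p_ns = config$p_ns)
    meta <- meta_analyze(diff, external,
                         n_internal = nrow(study$expression),
                         p_max = config$p_ns, fdr = config$fdr)
    stages <- c(stages, "concordance")
  }

  collection <- NULL
  if (!is.null(config$gmt_path)) {
    collection <- read_gene_sets(config$gmt_path)
  } else if (!is.null(truth)) {
    collection <- make_fixture_gene_sets(truth, seed = config$seed + 2000L)
  }
  enrichment <- projection <- pathway_diff <- NULL
  if (!is.null(collection)) {
    universe <- unique(study$aptamers$gene_symbol)
    sig_genes <- unique(
      diff$records$gene_symbol[diff$records$q < config$fdr])
    enrichment <- enrich(sig_genes, collection, universe)
    projection <- tryCatch(
      suppressWarnings(project_pathways(study, collection)),
      error = function(e) NULL)
    if (!is.null(projection)) {
      pathway_diff <- pathway_differential(projection, study,
                                           design = "three_group",
                                           fdr = config$pathway_fdr)
    }
    stages <- c(stages, "enrichment")
  }

  net <- NULL
  if (network) {
    ms_cent <- tryCatch(
      build_module_set(study, "centenarian", label = "CENT",
                       min_module_size = config$min_module_size),
      error = function(e) fail("network", e))
    ms_young <- build_module_set(study, c("offspring", "control"),
                                 label = "CTRL",
                                 min_module_size = config$min_module_size)
    graph <- build_module_graph(ms_cent, ms_young,
                                me_cor_threshold = config$me_cor,
                                jaccard_threshold = config$jaccard)
    net <- list(centenarian = ms_cent, younger = ms_young, graph = graph)
    stages <- c(stages, "network")
  }

  report <- list(
    study = study, truth = truth, qc_removed = qc$removed,
    differential = diff, offspring_contrast = offc,
    survival_labeling = labeling,
    survival_centenarians = surv_cent, survival_younger = surv_young,
    external = external, concordance = concordance, meta = meta,
    enrichment = enrichment, projection = projection,
    pathway_differential = pathway_diff, network = net,
    meta_info = list(seed = config$seed, fdr = config$fdr,
                     p_ns = config$p_ns,
                     survival_alpha = config$survival_alpha,
                     stages_run = stages,
                     survival_skipped = !"survival" %in% stages)
  )
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

# Write the report bundle's tables and a JSON summary.
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_results(report$differential$records,
                file.path(out_dir, "differential.tsv"))
  write_results(report$offspring_contrast$records,
                file.path(out_dir, "offspring_contrast.tsv"))
  if (!is.null(report$survival_centenarians)) {
    write_results(report$survival_centenarians$records,
                  file.path(out_dir, "survival_centenarians.tsv"))
  }
  if (!is.null(report$survival_younger)) {
    write_results(report$survival_younger$records,
                  file.path(out_dir, "survival_younger.tsv"))
  }
  if (!is.null(report$enrichment)) {
    write_results(report$enrichment, file.path(out_dir, "enrichment.tsv"))
  }
  summary <- list(
    n_samples = nrow(report$study$expression),
    n_aptamers = ncol(report$study$expression),
    qc_removed = report$qc_removed,
    signature_aptamers = report$differential$n_aptamers,
    signature_proteins = report$differential$n_proteins,
    signature_up = length(report$differential$up),
    signature_down = length(report$differential$down),
    signature_mixed = length(report$differential$mixed),
    offspring_significant = length(report$offspring_contrast$significant),
    survival_selected_centenarians =
      if (!is.null(report$survival_centenarians))
        length(report$survival_centenarians$selected) else NULL,
    survival_selected_younger =
      if (!is.null(report$survival_younger))
        length(report$survival_younger$selected) else NULL,
    concordance_table = if (!is.null(report$concordance))
      as.vector(report$concordance$table) else NULL,
    meta_significant = if (!is.null(report$meta))
      length(report$meta$significant) else NULL,
    n_modules_centenarian = if (!is.null(report$network))
      length(report$network$centenarian$modules) else NULL,
    n_modules_younger = if (!is.null(report$network))
      length(report$network$younger$modules) else NULL,
    stages_run = report$meta_info$stages_run
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Score a report against the simulation truth ledger
#'
#' Computes sensitivity and empirical FDR of the differential signature
#' and of the survival signatures against the planted effects.
#'
#' @param report output of [run_full_analysis()] on a simulated config.
#' @param truth truth ledger; defaults to the one inside the report.
#' @return list of recovery metrics.
#' @export
score_truth <- function(report, truth = report$truth) {
  if (is.null(truth)) stop2("no truth ledger available")
  ta <- truth$aptamers
  rec <- report$differential$records
  sig <- rec$aptamer_id[rec$q < report$meta_info$fdr]
  planted <- ta$aptamer_id[ta$planted_direction != "null"]
  tp <- length(intersect(sig, planted))
  sens <- if (length(planted) > 0) tp / length(planted) else NA_real_
  fdr_emp <- if (length(sig) > 0) 1 - tp / length(sig) else 0
  # direction agreement among detected planted aptamers
  det <- rec[rec$aptamer_id %in% intersect(sig, planted), ]
  tdir <- ta$planted_direction[match(det$aptamer_id, ta$aptamer_id)]
  dir_ok <- mean((tdir == "up") ==
                   (det$direction == "up_in_centenarians"))
  out <- list(differential = list(sensitivity = sens,
                                  empirical_fdr = fdr_emp,
                                  direction_agreement = dir_ok,
                                  n_selected = length(sig)))
  surv_planted <- ta$aptamer_id[ta$survival_effect != 0]
  for (nm in c("survival_centenarians", "survival_younger")) {
    sv <- report[[nm]]
    if (is.null(sv) || length(surv_planted) == 0) next
    tp <- length(intersect(sv$selected, surv_planted))
    out[[nm]] <- list(sensitivity = tp / length(surv_planted),
                      n_selected = length(sv$selected))
  }
  out
}
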