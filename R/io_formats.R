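# Reading, validating and writing the study inputs and result tables.
# All formats are plain text: TSV matrices and tables, GMT gene sets,
# YAML configs and JSON summaries.

#' Construct and validate a study object
#'
#' Bundles the strictly positive samples-by-aptamers RFU matrix with its
#' sample and aptamer annotation tables; identifiers are cross-checked and
#' rows/columns put in canonical (id-sorted) order.
#'
#' @param expression numeric matrix, samples in rows (rownames = sample
#'   ids), aptamers in columns (colnames = aptamer ids), raw RFU.
#' @param samples data.frame with columns `sample_id`, `group` (one of
#'   centenarian/offspring/control), `sex`, `age_at_draw`,
#'   `collection_year`, and optionally `survival_years`, `dead`.
#' @param aptamers data.frame with columns `aptamer_id`, `uniprot`,
#'   `gene_symbol`.
#' @return object of class `cent_study`.
#' @export
new_study <- function(expression, samples, aptamers) {
  if (!is.matrix(expression) || !is.numeric(expression)) {
    stop2("expression must be a numeric matrix")
  }
  req_s <- c("sample_id", "group", "sex", "age_at_draw", "collection_year")
  miss <- setdiff(req_s, names(samples))
  if (length(miss) > 0) stop2("samples table missing column(s): ",
                              paste(miss, collapse = ", "))
  req_a <- c("aptamer_id", "uniprot", "gene_symbol")
  miss <- setdiff(req_a, names(aptamers))
  if (length(miss) > 0) stop2("aptamer table missing column(s): ",
                              paste(miss, collapse = ", "))
  if (anyDuplicated(samples$sample_id)) stop2("duplicate sample ids")
  if (anyDuplicated(aptamers$aptamer_id)) stop2("duplicate aptamer ids")

  extra <- setdiff(rownames(expression), samples$sample_id)
  if (length(extra) > 0) {
    stop2("expression sample(s) absent from samples table: ",
          paste(utils::head(extra, 5), collapse = ", "))
  }
  extra <- setdiff(samples$sample_id, rownames(expression))
  if (length(extra) > 0) {
    stop2("samples table sample(s) absent from expression: ",
          paste(utils::head(extra, 5), collapse = ", "))
  }
  if (!setequal(colnames(expression), aptamers$aptamer_id)) {
    stop2("expression columns and aptamer table ids do not match")
  }
  as_group_factor(samples$group)

  bad <- which(!is.finite(expression) | expression <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop2("non-positive RFU value(s), e.g. aptamer ",
          colnames(expression)[bad[1, 2]], " in sample ",
          rownames(expression)[bad[1, 1]])
  }

  samples <- samples[order(samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  aptamers <- aptamers[order(aptamers$aptamer_id), , drop = FALSE]
  rownames(aptamers) <- NULL
  expression <- expression[samples$sample_id, aptamers$aptamer_id,
                           drop = FALSE]
  structure(list(expression = expression, samples = samples,
                 aptamers = aptamers), class = "cent_study")
}

#' @export
print.cent_study <- function(x, ...) {
  cat("cent_study:", nrow(x$expression), "samples x",
      ncol(x$expression), "aptamers\n")
  print(table(x$samples$group))
  invisible(x)
}

#' Log-transformed expression matrix of a study
#' @param study a `cent_study`.
#' @return samples-by-aptamers matrix of natural-log RFU.
#' @export
log_expr <- function(study) log(study$expression)

#' Load a study from TSV files
#'
#' @param expression_path TSV with a `sample_id` first column and one column
#'   per aptamer (raw RFU).
#' @param samples_path,aptamers_path annotation TSVs (see [new_study()]).
#' @return validated `cent_study` in canonical order.
#' @export
load_study <- function(expression_path, samples_path, aptamers_path) {
  for (p in c(expression_path, samples_path, aptamers_path)) {
    if (!file.exists(p)) stop2("file not found: ", p)
  }
  ex <- utils::read.delim(expression_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(ex)[1] != "sample_id") stop2("expression TSV must start with a sample_id column")
  mat <- as.matrix(ex[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- ex$sample_id
  samples <- utils::read.delim(samples_path, stringsAsFactors = FALSE)
  aptamers <- utils::read.delim(aptamers_path, stringsAsFactors = FALSE)
  new_study(mat, samples, aptamers)
}

#' Write a study to TSV files
#'
#' Inverse of [load_study()]; round-trips exactly in canonical order.
#'
#' @param study a `cent_study`.
#' @param dir output directory (created if needed).
#' @return invisibly, the three file paths.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("expression.tsv", "samples.tsv", "aptamers.tsv"))
  ex <- data.frame(sample_id = rownames(study$expression),
                   study$expression, check.names = FALSE)
  utils::write.table(ex, paths[1], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(study$samples, paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(study$aptamers, paths[3], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then member symbols. Duplicate symbols within a line are deduplicated;
#' empty sets are dropped with a warning.
#'
#' @param gmt_path path to the GMT file.
#' @return named list of character vectors (class `gene_set_collection`).
#' @export
read_gene_sets <- function(gmt_path) {
  if (!file.exists(gmt_path)) stop2("file not found: ", gmt_path)
  lines <- readLines(gmt_path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop2("malformed GMT line ", i, ": fewer than 3 tab-separated fields")
    }
    members <- unique(fields[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) == 0) {
      warning("dropping empty gene set '", fields[1], "' (line ", i, ")")
      next
    }
    sets[[fields[1]]] <- members
  }
  structure(sets, class = "gene_set_collection")
}

#' Write a gene-set collection as GMT
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional per-set description strings.
#' @export
write_gene_sets <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a results table as deterministic TSV
#'
#' Columns keep their input order; numeric columns are serialized with 6
#' significant digits; rows are sorted by p-value then id when those
#' columns are present, so repeated calls are byte-identical.
#'
#' @param records data.frame of results.
#' @param path output path.
#' @export
write_results <- function(records, path) {
  records <- as.data.frame(records)
  ord_cols <- intersect(c("p", "p_value"), names(records))
  id_cols <- intersect(c("aptamer_id", "set_name", "pathway", "id"),
                       names(records))
  if (nrow(records) > 0 && length(ord_cols) > 0) {
    o <- order(records[[ord_cols[1]]],
               if (length(id_cols) > 0) records[[id_cols[1]]] else NULL)
    records <- records[o, , drop = FALSE]
  }
  out <- records
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- format_signif(out[[j]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a simulation or run configuration as YAML
#' @param config a list (e.g. [sim_config()]).
#' @param path YAML path.
#' @export
write_config_yaml <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  yaml::read_yaml(path)
}

#' Write the truth ledger tables as TSV
#' @param truth truth ledger from [simulate_cohort()].
#' @param dir output directory.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(truth$aptamers, file.path(dir, "truth_aptamers.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(truth$samples, file.path(dir, "truth_samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
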