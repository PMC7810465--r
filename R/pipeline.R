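# End-to-end orchestration: a validated run configuration, input checking,
# and the qc -> subsample -> signatures -> translate -> fold changes ->
# staging -> severity pipeline with a machine-readable, byte-reproducible
# run report.

#' Build a pipeline run configuration
#'
#' Inputs may be given as file paths (MTX directory / TSV files, as written
#' by [write_sim_bundle()]) or as in-memory objects. Unspecified settings
#' take the pipeline defaults.
#'
#' @param counts MTX directory path or genes x cells matrix.
#' @param cell_metadata TSV path or data.frame (cell_id, timepoint_hr, ...).
#' @param query_counts TSV path or genes x samples matrix.
#' @param sample_metadata TSV path or data.frame (sample_id, is_reference).
#' @param orthologues TSV path or data.frame (mouse, human); `NULL` keeps
#'   gene ids untranslated.
#' @param severity TSV path or data.frame (sample_id, sofa); optional.
#' @param outdir output directory for artifacts and the report.
#' @param min_genes,max_genes,max_mito_percent QC thresholds.
#' @param n_subsample cells drawn per time point (default 2000).
#' @param seed integer seed used for every random draw in the run.
#' @param fdr_threshold signature FDR cutoff (default 0.05).
#' @param top_k concordance list length (default 500).
#' @param min_genes_for_rho minimum gene overlap per staging correlation.
#' @param prior_count prior count for fold changes.
#' @param fallback_dispersion dispersion for replicate-free comparisons.
#' @param stage_map coarse-label map (see [stage_queries()]).
#' @param expected_timepoints vocabulary checked by [validate_inputs()].
#' @return object of class `run_config`.
#' @export
run_config <- function(counts, cell_metadata, query_counts, sample_metadata,
                       orthologues = NULL, severity = NULL, outdir = NULL,
                       min_genes = 200, max_genes = 3000,
                       max_mito_percent = 50, n_subsample = 2000, seed = 999,
                       fdr_threshold = 0.05, top_k = 500,
                       min_genes_for_rho = 10, prior_count = 0.5,
                       fallback_dispersion = 0.1,
                       stage_map = default_stage_map(),
                       expected_timepoints = c(0, 1, 4, 16, 27, 36, 48)) {
  check_scalar(min_genes, "min_genes", lower = 0, integer = TRUE)
  check_scalar(max_genes, "max_genes", lower = min_genes, integer = TRUE)
  check_scalar(max_mito_percent, "max_mito_percent", lower = 0, upper = 100)
  check_scalar(n_subsample, "n_subsample", lower = 1, integer = TRUE)
  check_scalar(fdr_threshold, "fdr_threshold", lower = 0, upper = 1,
               strict_lower = TRUE)
  check_scalar(top_k, "top_k", lower = 1, integer = TRUE)
  check_scalar(min_genes_for_rho, "min_genes_for_rho", lower = 3,
               integer = TRUE)
  structure(list(counts = counts, cell_metadata = cell_metadata,
                 query_counts = query_counts,
                 sample_metadata = sample_metadata,
                 orthologues = orthologues, severity = severity,
                 outdir = outdir, min_genes = min_genes,
                 max_genes = max_genes, max_mito_percent = max_mito_percent,
                 n_subsample = n_subsample, seed = as.integer(seed),
                 fdr_threshold = fdr_threshold, top_k = top_k,
                 min_genes_for_rho = min_genes_for_rho,
                 prior_count = prior_count,
                 fallback_dispersion = fallback_dispersion,
                 stage_map = stage_map,
                 expected_timepoints = expected_timepoints),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Path-valued fields are interpreted relative to the YAML file's directory.
#'
#' @param path YAML file with keys matching [run_config()] arguments.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  rel <- function(p) {
    if (is.null(p) || !is.character(p)) return(p)
    ifelse(file.exists(p) | grepl("^/", p), p, file.path(base, p))
  }
  for (f in c("counts", "cell_metadata", "query_counts", "sample_metadata",
              "orthologues", "severity", "outdir")) {
    if (!is.null(raw[[f]])) raw[[f]] <- rel(raw[[f]])
  }
  do.call(run_config, raw)
}

# Materialize a config field: read from disk when given as a path.
load_input <- function(x, kind) {
  if (is.null(x)) return(NULL)
  if (is.character(x) && length(x) == 1L) {
    switch(kind,
           mtx = read_counts_mtx(x),
           counts_tsv = read_counts_tsv(x),
           tsv = read_tsv(x))
  } else x
}

#' Check a run configuration and its inputs for problems
#'
#' Returns issues as a character vector instead of raising; an empty vector
#' means the configuration is runnable. Checks file readability,
#' matrix/metadata consistency, the time-point vocabulary, the >= 2
#' reference-sample requirement and the orthologue-map format.
#'
#' @param config a `run_config`.
#' @return character vector of issues (empty if none).
#' @export
validate_inputs <- function(config) {
  if (!inherits(config, "run_config")) {
    return("config must be created by run_config() or read_run_config()")
  }
  issues <- character(0)
  add <- function(msg) issues <<- c(issues, msg)

  path_fields <- list(counts = "counts", cell_metadata = "cell_metadata",
                      query_counts = "query_counts",
                      sample_metadata = "sample_metadata",
                      orthologues = "orthologues", severity = "severity")
  for (f in names(path_fields)) {
    x <- config[[f]]
    if (is.character(x) && length(x) == 1L && !file.exists(x)) {
      add(sprintf("input path for '%s' not readable: %s", f, x))
    }
  }
  if (length(issues)) return(issues)

  counts <- tryCatch(load_input(config$counts, "mtx"), error = function(e) e)
  if (inherits(counts, "error")) {
    add(paste("counts:", conditionMessage(counts)))
    return(issues)
  }
  meta <- load_input(config$cell_metadata, "tsv")
  if (!all(c("cell_id", "timepoint_hr") %in% names(meta))) {
    add("cell metadata must have columns cell_id and timepoint_hr")
  } else {
    missing <- setdiff(colnames(counts), meta$cell_id)
    if (length(missing)) {
      add(sprintf("metadata missing for %d cell(s), e.g. %s",
                  length(missing), missing[1]))
    }
    bad_tp <- setdiff(unique(meta$timepoint_hr), config$expected_timepoints)
    if (length(bad_tp)) {
      add(sprintf("unexpected time point(s): %s (expected %s)",
                  paste(bad_tp, collapse = ", "),
                  paste(config$expected_timepoints, collapse = ", ")))
    }
  }
  query <- load_input(config$query_counts, "counts_tsv")
  smeta <- load_input(config$sample_metadata, "tsv")
  if (!all(c("sample_id", "is_reference") %in% names(smeta))) {
    add("sample metadata must have columns sample_id and is_reference")
  } else {
    n_ref <- sum(as.logical(smeta$is_reference))
    if (n_ref < 2L) {
      add(sprintf("%d reference sample(s); at least 2 are required", n_ref))
    }
    miss_q <- setdiff(colnames(query), smeta$sample_id)
    if (length(miss_q)) {
      add(sprintf("sample metadata missing for %d column(s), e.g. %s",
                  length(miss_q), miss_q[1]))
    }
  }
  if (!is.null(config$orthologues)) {
    omap <- load_input(config$orthologues, "tsv")
    if (!all(c("mouse", "human") %in% names(omap))) {
      add("orthologue map must have columns mouse and human")
    }
  }
  if (!is.null(config$severity)) {
    sev <- load_input(config$severity, "tsv")
    if (!all(c("sample_id", "sofa") %in% names(sev))) {
      add("severity table must have columns sample_id and sofa")
    }
  }
  issues
}

#' Run the staging pipeline end-to-end
#'
#' Executes QC filtering, seeded per-time-point subsampling, one-vs-rest
#' signature derivation, orthologue translation, query fold changes versus
#' the reference mean, Spearman staging, and (when severity scores are
#' provided) the stage-severity association. Writes the signature tables,
#' staging matrix, assignments and a JSON run report to `outdir`, and
#' returns the report. Identical inputs, config and seed give byte-identical
#' artifacts.
#'
#' @param config a `run_config` (or YAML path).
#' @return the run report (list), invisibly; its `staging` element holds the
#'   fitted `staging` object.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  issues <- validate_inputs(config)
  if (length(issues)) {
    stop("invalid configuration:\n  - ", paste(issues, collapse = "\n  - "),
         call. = FALSE)
  }
  warnings_log <- character(0)
  collect <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      warnings_log <<- c(warnings_log, conditionMessage(w))
      invokeRestart("muffleWarning")
    }, message = function(m) {
      warnings_log <<- c(warnings_log, sub("\n$", "", conditionMessage(m)))
      invokeRestart("muffleMessage")
    })
  }

  counts <- load_input(config$counts, "mtx")
  meta <- load_input(config$cell_metadata, "tsv")
  query <- load_input(config$query_counts, "counts_tsv")
  smeta <- load_input(config$sample_metadata, "tsv")
  omap <- load_input(config$orthologues, "tsv")
  sev <- load_input(config$severity, "tsv")

  report <- list(package = "sepstager",
                 version = as.character(utils::packageVersion("sepstager")),
                 seed = config$seed)
  report$input_dim <- list(sc = dim(counts), query = dim(query))

  # 1. QC
  flt <- collect(qc_filter(counts, meta, config$min_genes, config$max_genes,
                           config$max_mito_percent))
  report$qc <- list(cells_in = ncol(counts), cells_kept = ncol(flt$counts))

  # 2. seeded subsampling per time point
  sel <- collect(subsample_cells(flt$meta, n = config$n_subsample,
                                 seed = config$seed))
  report$subsample <- lapply(sel, length)

  sub_counts <- flt$counts[, unlist(sel, use.names = FALSE), drop = FALSE]
  sub_groups <- rep(names(sel), lengths(sel))

  # 3. TMM + dispersion + one-vs-rest signatures
  norm <- tmm_factors(sub_counts)
  disp <- estimate_dispersion(sub_counts, sub_groups, norm,
                              fallback_dispersion = config$fallback_dispersion)
  sigs <- collect(timepoint_signatures(sub_counts, sub_groups, norm, disp,
                                       q = config$fdr_threshold,
                                       prior_count = config$prior_count))
  report$signature_sizes <- lapply(sigs, function(s) length(s$genes))
  report$dispersion_common <- disp$common

  # 4. orthologue translation
  if (!is.null(omap)) {
    sigs <- collect(lapply(sigs, translate_signature, map = omap))
    report$translated_sizes <- lapply(sigs, function(s) length(s$genes))
  }

  # 5. query fold changes vs reference mean
  ref_ids <- smeta$sample_id[as.logical(smeta$is_reference)]
  qfc <- query_foldchange(query, ref_ids, prior_count = config$prior_count)
  report$n_query <- length(qfc)
  report$n_reference <- length(ref_ids)

  # 6. staging
  staging <- collect(stage_queries(sigs, qfc,
                                   min_genes = config$min_genes_for_rho,
                                   stage_map = config$stage_map))
  report$assignments <- staging$assignments

  # 7. severity association
  if (!is.null(sev)) {
    assoc <- collect(severity_association(staging, sev, seed = config$seed))
    report$severity <- list(rho = unname(assoc$estimate),
                            p_value = assoc$p.value)
  }
  report$warnings <- warnings_log

  if (!is.null(config$outdir)) {
    write_run_artifacts(report, staging, sigs, config$outdir)
  }
  report$staging <- staging
  invisible(report)
}

# Write the pipeline artifacts deterministically.
write_run_artifacts <- function(report, staging, sigs, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  sig_rows <- do.call(rbind, lapply(sigs, function(s) {
    if (!length(s$genes)) return(NULL)
    data.frame(timepoint_hr = s$timepoint_hr, gene_id = s$genes,
               log2fc = round(unname(s$log2fc), 6), stringsAsFactors = FALSE)
  }))
  if (!is.null(sig_rows)) write_tsv(sig_rows, file.path(outdir, "signatures.tsv"))

  rho_df <- data.frame(sample_id = rownames(staging$rho),
                       round(staging$rho, 6), check.names = FALSE,
                       stringsAsFactors = FALSE)
  write_tsv(rho_df, file.path(outdir, "staging_matrix.tsv"))
  a <- staging$assignments
  a$best_rho <- round(a$best_rho, 6)
  write_tsv(a, file.path(outdir, "assignments.tsv"))

  # heatmap-ready long format
  long <- data.frame(
    sample_id = rep(rownames(staging$rho), ncol(staging$rho)),
    timepoint_hr = rep(colnames(staging$rho), each = nrow(staging$rho)),
    rho = round(as.vector(staging$rho), 6),
    n_genes_used = as.vector(staging$n_genes_used),
    stringsAsFactors = FALSE)
  write_tsv(long, file.path(outdir, "staging_long.tsv"))

  json_report <- report
  json_report$assignments <- NULL
  jsonlite::write_json(json_report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(outdir)
}
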