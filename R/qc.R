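#' Filter cells on detected genes and mitochondrial percentage
#'
#' Retains cells with `min_genes <= n_genes_detected <= max_genes` (bounds
#' inclusive) and `mito_percent < max_mito_percent` (strict), the standard
#' doublet / low-quality exclusion. When the metadata lacks
#' `n_genes_detected` or `mito_percent` they are recomputed from the matrix;
#' mitochondrial genes are identified by an id prefix (default `"mt-"`,
#' case-insensitive). Column order is preserved, and filtering is
#' idempotent.
#'
#' @param counts genes x cells count matrix.
#' @param meta per-cell metadata with a `cell_id` column covering every
#'   column of `counts`.
#' @param min_genes,max_genes inclusive bounds on detected genes per cell.
#' @param max_mito_percent strict upper bound on mitochondrial percentage.
#' @param mito_prefix gene-id prefix marking mitochondrial genes.
#' @return list with the filtered `counts` and `meta`.
#' @examples
#' sim <- simulate_timecourse(sim_config(n_genes = 300,
#'                                       n_cells_per_timepoint = 30, seed = 1))
#' flt <- qc_filter(sim$counts, sim$meta)
#' ncol(flt$counts)
#' @export
qc_filter <- function(counts, meta, min_genes = 200, max_genes = 3000,
                      max_mito_percent = 50, mito_prefix = "mt-") {
  counts <- check_counts(counts)
  if (!"cell_id" %in% names(meta)) stop("'meta' needs a cell_id column",
                                        call. = FALSE)
  missing <- setdiff(colnames(counts), meta$cell_id)
  if (length(missing)) {
    stop("metadata missing for cell(s): ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) sprintf(" (and %d more)", length(missing) - 5),
         call. = FALSE)
  }
  meta <- meta[match(colnames(counts), meta$cell_id), , drop = FALSE]
  if (!"n_genes_detected" %in% names(meta)) {
    meta$n_genes_detected <- colSums(counts > 0)
  }
  if (!"mito_percent" %in% names(meta)) {
    is_mito <- startsWith(tolower(rownames(counts)), tolower(mito_prefix))
    tot <- colSums(counts)
    meta$mito_percent <- if (any(is_mito)) {
      100 * colSums(counts[is_mito, , drop = FALSE]) / pmax(tot, 1)
    } else 0
  }
  keep <- meta$n_genes_detected >= min_genes &
    meta$n_genes_detected <= max_genes &
    meta$mito_percent < max_mito_percent
  message(sprintf("qc_filter: kept %d of %d cells (%d removed)",
                  sum(keep), length(keep), sum(!keep)))
  out_meta <- meta[keep, , drop = FALSE]
  rownames(out_meta) <- NULL
  list(counts = counts[, keep, drop = FALSE], meta = out_meta)
}

#' Library-size log-normalization
#'
#' Each entry becomes `ln(1 + scale * count / column_sum)`, i.e. counts are
#' scaled to a common depth of `scale` (default 1e4) per column and
#' log1p-transformed.
#'
#' @param counts genes x columns count matrix with no all-zero columns.
#' @param scale target depth per column.
#' @return real-valued matrix of the same shape.
#' @export
lognormalize <- function(counts, scale = 1e4) {
  counts <- check_counts(counts)
  cs <- colSums(counts)
  if (any(cs == 0)) {
    stop("column(s) with zero total counts: ",
         paste(utils::head(colnames(counts)[cs == 0], 5), collapse = ", "),
         call. = FALSE)
  }
  log1p(sweep(counts, 2, scale / cs, "*"))
}

#' Seeded per-group subsampling of cells
#'
#' Draws, for each group (time point by default), a uniform random sample of
#' `n` cell ids without replacement. Groups smaller than `n` are returned
#' whole with a warning. The draw is deterministic given `seed`: groups are
#' visited in sorted order under a fixed Mersenne-Twister state.
#'
#' @param meta per-cell metadata with `cell_id` and the grouping column.
#' @param n cells to draw per group.
#' @param seed integer seed (default 999).
#' @param group_by name of the grouping column (default `"timepoint_hr"`).
#' @return named list of character vectors of cell ids, one per group.
#' @export
subsample_cells <- function(meta, n = 2000, seed = 999,
                            group_by = "timepoint_hr") {
  if (!all(c("cell_id", group_by) %in% names(meta))) {
    stop("'meta' needs columns cell_id and ", group_by, call. = FALSE)
  }
  check_scalar(n, "n", lower = 1, integer = TRUE)
  groups <- split(meta$cell_id, meta[[group_by]])
  empty <- names(groups)[lengths(groups) == 0L]
  if (length(empty)) stop("empty group(s): ", paste(empty, collapse = ", "),
                          call. = FALSE)
  ord <- order(suppressWarnings(as.numeric(names(groups))), names(groups),
               na.last = TRUE)
  groups <- groups[ord]
  with_seed(seed, {
    out <- lapply(names(groups), function(g) {
      ids <- groups[[g]]
      if (length(ids) <= n) {
        if (length(ids) < n) {
          warning(sprintf("group '%s' has %d cells (< n = %d); returned whole",
                          g, length(ids), n), call. = FALSE)
        }
        ids
      } else {
        sample(ids, n)
      }
    })
    names(out) <- names(groups)
    out
  })
}

#' Aggregate selected cells into per-group pseudobulk columns
#'
#' Each group column is the elementwise sum of its member cells' counts, so
#' total counts of the selected cells are conserved exactly.
#'
#' @param counts genes x cells count matrix.
#' @param selection named list of cell-id vectors (e.g. from
#'   [subsample_cells()]).
#' @return genes x groups integer matrix with attribute `n_cells`
#'   (cells per group).
#' @export
pseudobulk <- function(counts, selection) {
  counts <- check_counts(counts)
  if (!is.list(selection) || is.null(names(selection))) {
    stop("'selection' must be a named list of cell ids", call. = FALSE)
  }
  unknown <- setdiff(unlist(selection), colnames(counts))
  if (length(unknown)) {
    stop("unknown cell id(s): ", paste(utils::head(unknown, 5), collapse = ", "),
         call. = FALSE)
  }
  out <- vapply(selection, function(ids) {
    rowSums(counts[, ids, drop = FALSE])
  }, numeric(nrow(counts)))
  dimnames(out) <- list(rownames(counts), names(selection))
  attr(out, "n_cells") <- lengths(selection)
  out
}
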