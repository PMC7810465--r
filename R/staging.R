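# Cross-species staging: derive per-time-point signatures from the mouse
# time course, translate them to human orthologues, compute query fold
# changes versus the reference-sample mean, and assign each query the time
# point whose signature its fold changes track best (Spearman).

default_stage_map <- function() {
  list(early = c(0, 1, 4), mid = 16, late = c(27, 36, 48))
}

#' Derive per-time-point one-vs-rest signatures
#'
#' For each time point, runs the NB one-vs-rest test on cells-as-replicates
#' and keeps the genes significant at `fdr < q`, with their signed log2 fold
#' changes (target time point versus all other time points pooled). A time
#' point with no significant gene yields an empty signature with a warning.
#'
#' @param counts genes x cells count matrix (typically the seeded 2000-cell
#'   subsample).
#' @param groups per-cell time point vector.
#' @param norm `norm_factors`; `NULL` computes TMM internally once.
#' @param disp `dispersion_estimate`; `NULL` estimates internally once.
#' @param q FDR threshold (default 0.05).
#' @param prior_count prior count for fold changes.
#' @return named list of `timepoint_signature` objects: each a list with
#'   `timepoint_hr`, `genes`, and `log2fc` (named by gene).
#' @export
timepoint_signatures <- function(counts, groups, norm = NULL, disp = NULL,
                                 q = 0.05, prior_count = 0.5) {
  counts <- check_counts(counts)
  groups <- as.character(groups)
  if (is.null(norm)) norm <- tmm_factors(counts)
  if (is.null(disp)) disp <- estimate_dispersion(counts, groups, norm)
  tps <- unique(groups)
  tps <- tps[order(suppressWarnings(as.numeric(tps)), tps)]
  sigs <- lapply(tps, function(tp) {
    res <- nb_test(counts, groups, tp, norm = norm, disp = disp,
                   prior_count = prior_count)
    sig <- significant_genes(res, q = q)
    if (!nrow(sig)) {
      warning("time point ", tp, ": no significant genes; empty signature",
              call. = FALSE)
    }
    structure(list(timepoint_hr = suppressWarnings(as.numeric(tp)),
                   genes = sig$gene_id,
                   log2fc = stats::setNames(sig$log2fc, sig$gene_id)),
              class = "timepoint_signature")
  })
  names(sigs) <- tps
  sigs
}

#' Resolve an orthologue map to its unambiguous one-to-one pairs
#'
#' Keeps only pairs whose mouse gene maps to exactly one human gene and
#' whose human gene is hit by exactly one mouse gene; ambiguous
#' (one-to-many / many-to-one) pairs are dropped with a message. This is the
#' conservative collision rule used throughout the staging branch.
#'
#' @param map data.frame with columns `mouse` and `human`.
#' @return data.frame of retained one-to-one pairs.
#' @export
resolve_orthologues <- function(map) {
  if (!is.data.frame(map) || !all(c("mouse", "human") %in% names(map))) {
    stop("orthologue map must have columns 'mouse' and 'human'", call. = FALSE)
  }
  map <- unique(map[, c("mouse", "human")])
  m_tab <- table(map$mouse)
  h_tab <- table(map$human)
  keep <- m_tab[map$mouse] == 1L & h_tab[map$human] == 1L
  dropped <- sum(!keep)
  if (dropped) message("resolve_orthologues: dropped ", dropped,
                       " ambiguous pair(s)")
  out <- map[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Translate a mouse signature to human gene ids
#'
#' Re-keys a signature through a (resolved, one-to-one) orthologue map;
#' unmapped genes are dropped with a message, fold changes carry over
#' unchanged. An empty translation is an error.
#'
#' @param sig a `timepoint_signature` (see [timepoint_signatures()]).
#' @param map orthologue map (resolved internally with
#'   [resolve_orthologues()]).
#' @return the translated `timepoint_signature` with human gene ids.
#' @export
translate_signature <- function(sig, map) {
  if (!inherits(sig, "timepoint_signature")) {
    stop("'sig' must be a timepoint_signature", call. = FALSE)
  }
  map <- resolve_orthologues(map)
  hit <- match(sig$genes, map$mouse)
  kept <- !is.na(hit)
  n_drop <- sum(!kept)
  if (n_drop) {
    message("translate_signature: ", n_drop, " gene(s) without orthologue ",
            "dropped (time point ", sig$timepoint_hr, ")")
  }
  if (!any(kept)) {
    stop("no orthologues for time point ", sig$timepoint_hr, call. = FALSE)
  }
  human <- map$human[hit[kept]]
  structure(list(timepoint_hr = sig$timepoint_hr,
                 genes = human,
                 log2fc = stats::setNames(unname(sig$log2fc[sig$genes[kept]]),
                                          human)),
            class = "timepoint_signature")
}

#' Per-sample fold changes versus the reference mean
#'
#' Each query sample's genes get `log2((cpm_sample + prior) /
#' (mean reference cpm + prior))`, with counts-per-million computed on plain
#' library sizes; the reference mean is taken across all reference samples
#' (at least two).
#'
#' @param counts genes x samples bulk count matrix (queries and references).
#' @param reference_ids sample ids of the reference columns (>= 2).
#' @param prior_count prior added to both cpm terms (default 0.5).
#' @return named list of `query_foldchange` objects (one per non-reference
#'   sample): each has `sample_id`, `log2fc` (named per gene), `n_reference`.
#' @export
query_foldchange <- function(counts, reference_ids, prior_count = 0.5) {
  counts <- check_counts(counts)
  reference_ids <- as.character(reference_ids)
  if (length(reference_ids) < 2L) {
    stop("at least 2 reference samples are required", call. = FALSE)
  }
  missing <- setdiff(reference_ids, colnames(counts))
  if (length(missing)) {
    stop("reference sample(s) not in matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  lib <- colSums(counts)
  if (any(lib == 0)) stop("sample(s) with zero total counts", call. = FALSE)
  cpm <- sweep(counts, 2, 1e6 / lib, "*")
  ref_mean <- rowMeans(cpm[, reference_ids, drop = FALSE])
  query_ids <- setdiff(colnames(counts), reference_ids)
  out <- lapply(query_ids, function(s) {
    structure(list(sample_id = s,
                   log2fc = stats::setNames(
                     log2((cpm[, s] + prior_count) / (ref_mean + prior_count)),
                     rownames(counts)),
                   n_reference = length(reference_ids)),
              class = "query_foldchange")
  })
  names(out) <- query_ids
  out
}

#' Spearman rank correlation (mid-ranks for ties)
#'
#' Pearson correlation of mid-ranks. A constant vector has no rank ordering:
#' the result is `NaN` with a warning, and staging excludes such cells from
#' the argmax.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return correlation in \[-1, 1\], or `NaN` for degenerate input.
#' @examples
#' spearman_rho(c(1, 2, 3, 4), c(1, 3, 2, 4)) # 0.8
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 paired observations", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector: Spearman correlation undefined", call. = FALSE)
    return(NaN)
  }
  stats::cor(rank(x), rank(y))
}

#' Stage query samples against the time-point signatures
#'
#' The central estimator: for every (query sample, time point) pair, the
#' Spearman correlation between the signature's mouse log2 fold changes and
#' the query's log2 fold changes over the signature genes present in the
#' query universe. Each sample is assigned the time point with the highest
#' correlation (ties broken toward the earliest hour) and a coarse
#' early/mid/late label. Cells with fewer than `min_genes` overlapping genes
#' are set to `NaN` with a warning and excluded from the argmax.
#'
#' @param sigs list of (translated) `timepoint_signature` objects.
#' @param queries list of `query_foldchange` objects.
#' @param min_genes minimum signature/query gene overlap per correlation.
#' @param stage_map named list mapping coarse labels to hours; default
#'   early = {0, 1, 4}, mid = {16}, late = {27, 36, 48}.
#' @return object of class `staging`: list with `rho` (samples x time
#'   points), `n_genes_used`, `assignments` data.frame (`sample_id`,
#'   `assigned_stage_hr`, `coarse_label`, `best_rho`, `n_genes_used`), and
#'   the `stage_map`.
#' @seealso [severity_association()], [plot.staging()]
#' @export
stage_queries <- function(sigs, queries, min_genes = 10,
                          stage_map = default_stage_map()) {
  if (!length(sigs)) stop("no signatures supplied", call. = FALSE)
  sigs <- sigs[vapply(sigs, function(s) length(s$genes) > 0, logical(1))]
  if (!length(sigs)) stop("all signatures are empty", call. = FALSE)
  if (!length(queries)) stop("no query samples supplied", call. = FALSE)
  check_scalar(min_genes, "min_genes", lower = 3, integer = TRUE)

  tps <- vapply(sigs, `[[`, numeric(1), "timepoint_hr")
  ord <- order(tps)
  sigs <- sigs[ord]; tps <- tps[ord]
  sample_ids <- vapply(queries, `[[`, character(1), "sample_id")

  rho <- matrix(NaN, nrow = length(queries), ncol = length(sigs),
                dimnames = list(sample_ids, as.character(tps)))
  n_used <- matrix(0L, nrow = length(queries), ncol = length(sigs),
                   dimnames = dimnames(rho))
  for (i in seq_along(queries)) {
    q <- queries[[i]]
    for (j in seq_along(sigs)) {
      common <- intersect(sigs[[j]]$genes, names(q$log2fc))
      n_used[i, j] <- length(common)
      if (length(common) < min_genes) {
        warning(sprintf("sample %s / time point %s: only %d overlapping genes (< %d)",
                        q$sample_id, tps[j], length(common), min_genes),
                call. = FALSE)
        next
      }
      rho[i, j] <- spearman_rho(sigs[[j]]$log2fc[common], q$log2fc[common])
    }
  }

  label_of <- function(hr) {
    hit <- names(stage_map)[vapply(stage_map, function(h) hr %in% h, logical(1))]
    if (length(hit)) hit[1] else NA_character_
  }
  assign_row <- function(r) {
    ok <- which(is.finite(r))
    if (!length(ok)) return(NA_integer_)
    best <- max(r[ok])
    # earliest hour among the maxima (columns are in increasing hour order)
    ok[which(r[ok] >= best - 1e-12)][1]
  }
  pick <- apply(rho, 1, assign_row)
  assigned <- ifelse(is.na(pick), NA_real_, tps[pick])
  best_rho <- vapply(seq_along(pick), function(i) {
    if (is.na(pick[i])) NA_real_ else rho[i, pick[i]]
  }, numeric(1))
  n_at <- vapply(seq_along(pick), function(i) {
    if (is.na(pick[i])) NA_integer_ else n_used[i, pick[i]]
  }, integer(1))

  assignments <- data.frame(
    sample_id = sample_ids,
    assigned_stage_hr = assigned,
    coarse_label = vapply(assigned, function(h) {
      if (is.na(h)) NA_character_ else label_of(h)
    }, character(1)),
    best_rho = best_rho,
    n_genes_used = n_at,
    stringsAsFactors = FALSE
  )
  structure(list(rho = rho, n_genes_used = n_used,
                 assignments = assignments, stage_map = stage_map,
                 timepoints = tps),
            class = "staging")
}

#' @export
print.staging <- function(x, ...) {
  cat("Staging of", nrow(x$rho), "query samples against",
      ncol(x$rho), "time-point signatures\n")
  cat("Time points (hr):", paste(x$timepoints, collapse = ", "), "\n")
  tab <- table(factor(x$assignments$assigned_stage_hr, levels = x$timepoints))
  cat("Assigned stages:\n")
  print(tab)
  invisible(x)
}

#' @export
summary.staging <- function(object, ...) {
  cat("Spearman rho, samples x time points (first rows):\n")
  print(utils::head(round(object$rho, 3)))
  cat("\nCoarse labels:\n")
  print(table(object$assignments$coarse_label, useNA = "ifany"))
  invisible(object)
}

#' @export
as.data.frame.staging <- function(x, ...) x$assignments

#' Heatmap of the staging correlation matrix
#'
#' Samples (rows, ordered by assigned stage) by time points (columns), with
#' the Spearman correlation as color.
#'
#' @param x a `staging` object.
#' @param ... passed to [graphics::image()].
#' @export
plot.staging <- function(x, ...) {
  ord <- order(x$assignments$assigned_stage_hr, -x$assignments$best_rho,
               na.last = TRUE)
  m <- x$rho[ord, , drop = FALSE]
  pal <- grDevices::hcl.colors(51, "RdBu", rev = TRUE)
  rng <- max(abs(m[is.finite(m)]), 1e-6)
  graphics::image(x = seq_len(ncol(m)), y = seq_len(nrow(m)), z = t(m),
                  col = pal, zlim = c(-rng, rng), axes = FALSE,
                  xlab = "time point (hr)", ylab = "query sample", ...)
  graphics::axis(1, at = seq_len(ncol(m)), labels = colnames(m))
  graphics::box()
  invisible(x)
}

#' Association between assigned stage and severity (SOFA)
#'
#' Spearman correlation between the assigned stage rank and the SOFA score,
#' with a seeded permutation p-value (two-sided: fraction of permutations
#' with |rho| at least as large, with the +1 correction).
#'
#' @param staging a `staging` object from [stage_queries()].
#' @param severity data.frame with `sample_id` and `sofa`.
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed for the permutations.
#' @return an object of class `htest` with the Spearman rho estimate and
#'   permutation p-value.
#' @export
severity_association <- function(staging, severity, n_perm = 10000,
                                 seed = 999) {
  if (!inherits(staging, "staging")) stop("'staging' must be a staging object",
                                          call. = FALSE)
  if (!all(c("sample_id", "sofa") %in% names(severity))) {
    stop("'severity' needs columns sample_id and sofa", call. = FALSE)
  }
  a <- staging$assignments
  merged <- merge(a[!is.na(a$assigned_stage_hr),
                    c("sample_id", "assigned_stage_hr")],
                  severity, by = "sample_id")
  if (nrow(merged) < 4L) {
    stop("fewer than 4 samples with both stage and severity", call. = FALSE)
  }
  stage_rank <- match(merged$assigned_stage_hr, sort(unique(staging$timepoints)))
  rho <- spearman_rho(stage_rank, merged$sofa)
  rs <- rank(stage_rank)
  rf <- rank(merged$sofa)
  p <- with_seed(seed, {
    perm <- replicate(n_perm, stats::cor(rs, sample(rf)))
    (sum(abs(perm) >= abs(rho) - 1e-12) + 1) / (n_perm + 1)
  })
  structure(list(
    statistic = c(S = sum((rs - rf)^2)),
    estimate = c(rho = rho),
    p.value = p,
    method = "Spearman correlation between assigned stage and SOFA (permutation test)",
    data.name = sprintf("%d samples, %d permutations", nrow(merged), n_perm)
  ), class = "htest")
}
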