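# Pseudobulk-versus-bulk concordance: pairwise one-vs-one DE between
# conditions, FDR-sorted top-k up/down gene lists, pairwise Jaccard
# matrices, and a directly implemented complete-linkage ordering for the
# heatmap.

#' Pairwise one-vs-one differential expression between conditions
#'
#' Runs the NB engine for each (unordered) pair of pseudobulk or bulk
#' columns. With single columns per condition there are no replicates, so a
#' fixed fallback dispersion is used.
#'
#' @param counts genes x conditions count matrix (one column per condition,
#'   or several with a `groups` vector).
#' @param pairs optional list of length-2 character vectors; default all
#'   unordered pairs of conditions.
#' @param groups per-column condition labels; default the column names.
#' @param dispersion fallback dispersion for replicate-free comparisons.
#' @param norm `norm_factors` over all columns; `NULL` computes TMM.
#' @return named list of [nb_test()] result data.frames, keyed
#'   `"A_vs_B"`.
#' @export
pairwise_de <- function(counts, pairs = NULL, groups = NULL,
                        dispersion = 0.1, norm = NULL) {
  counts <- check_counts(counts)
  groups <- as.character(groups %||% colnames(counts))
  conds <- unique(groups)
  if (is.null(pairs)) {
    pairs <- utils::combn(conds, 2, simplify = FALSE)
  }
  for (p in pairs) {
    miss <- setdiff(p, conds)
    if (length(miss)) stop("condition not present: ", paste(miss, collapse = ", "),
                           call. = FALSE)
  }
  if (is.null(norm)) norm <- tmm_factors(counts)
  disp <- structure(list(common = dispersion,
                         tagwise = stats::setNames(rep(dispersion, nrow(counts)),
                                                   rownames(counts)),
                         shrinkage_weight = 1),
                    class = "dispersion_estimate")
  out <- lapply(pairs, function(p) {
    nb_test(counts, groups, target_group = p[1], other_group = p[2],
            norm = norm, disp = disp)
  })
  names(out) <- vapply(pairs, function(p) paste(p[1], "vs", p[2], sep = "_"),
                       character(1))
  out
}

#' Split DE results into FDR-ranked top-k up and down gene lists
#'
#' Results are sorted by FDR ascending (ties broken by |log2fc| descending,
#' then gene id, for a deterministic total order), partitioned by the sign
#' of the fold change, and each partition truncated to `k`. Genes with
#' log2fc exactly 0 belong to neither list.
#'
#' @param results data.frame from [nb_test()].
#' @param k list-length cap (default 500).
#' @param comparison_id identifier stored with the lists.
#' @return object of class `directional_gene_lists`: list with
#'   `comparison_id`, `up`, `down` (ordered gene-id vectors), `k`.
#' @export
top_k_split <- function(results, k = 500, comparison_id = "comparison") {
  stopifnot(all(c("gene_id", "log2fc", "fdr") %in% names(results)))
  check_scalar(k, "k", lower = 1, integer = TRUE)
  if (any(!is.finite(results$fdr))) stop("non-finite FDR values", call. = FALSE)
  ord <- order(results$fdr, -abs(results$log2fc), results$gene_id)
  res <- results[ord, , drop = FALSE]
  up <- res$gene_id[res$log2fc > 0]
  down <- res$gene_id[res$log2fc < 0]
  structure(list(comparison_id = comparison_id,
                 up = utils::head(up, k),
                 down = utils::head(down, k),
                 k = as.integer(k)),
            class = "directional_gene_lists")
}

#' Jaccard index of two gene sets
#'
#' `|a n b| / |a u b|`; two empty sets give 1 by convention, with a warning
#' flagging the vacuous comparison.
#'
#' @param a,b character vectors (treated as sets).
#' @return real in \[0, 1\].
#' @examples
#' jaccard(c("A", "B", "C"), c("B", "C", "D")) # 0.5
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) {
    warning("both sets empty: Jaccard defined as 1", call. = FALSE)
    return(1)
  }
  length(intersect(a, b)) / u
}

#' Pairwise Jaccard matrix with complete-linkage ordering
#'
#' Builds the symmetric comparisons x comparisons Jaccard matrix over the
#' chosen direction's gene lists and orders rows/columns by complete-linkage
#' agglomerative clustering on distance `1 - J` (naive direct
#' implementation; ties broken lexicographically on comparison id).
#'
#' @param lists list of `directional_gene_lists` (see [top_k_split()]).
#' @param direction `"up"` or `"down"`.
#' @return object of class `jaccard_result`: list with `matrix`,
#'   `linkage_order` (comparison ids in dendrogram leaf order), `merges`
#'   (merge heights), `direction`.
#' @export
jaccard_heatmap <- function(lists, direction = c("up", "down")) {
  direction <- match.arg(direction)
  if (length(lists) < 2L) stop("need at least 2 comparisons", call. = FALSE)
  ids <- vapply(lists, `[[`, character(1), "comparison_id")
  if (anyDuplicated(ids)) stop("duplicated comparison ids", call. = FALSE)
  sets <- lapply(lists, `[[`, direction)
  n <- length(sets)
  m <- diag(1, n)
  dimnames(m) <- list(ids, ids)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      m[i, j] <- m[j, i] <- jaccard(sets[[i]], sets[[j]])
    }
  }
  cl <- complete_linkage(1 - m, ids)
  structure(list(matrix = m, linkage_order = cl$order, merges = cl$merges,
                 direction = direction),
            class = "jaccard_result")
}

# Naive O(n^3) complete-linkage agglomeration on a distance matrix.
# Deterministic: among equidistant cluster pairs the lexicographically
# smallest (by each cluster's smallest member label) is merged first, and a
# merged cluster's leaf order puts the lexicographically smaller side left.
complete_linkage <- function(d, labels) {
  stopifnot(is.matrix(d), nrow(d) == length(labels))
  n <- length(labels)
  clusters <- lapply(seq_len(n), identity)      # member indices
  keys <- labels                                # tie-break key per cluster
  merges <- list()
  while (length(clusters) > 1L) {
    k <- length(clusters)
    best <- NULL
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        h <- max(d[clusters[[i]], clusters[[j]]])
        pair_key <- paste(sort(c(keys[i], keys[j])), collapse = "\r")
        if (is.null(best) || h < best$h - 1e-15 ||
            (abs(h - best$h) <= 1e-15 && pair_key < best$key)) {
          best <- list(i = i, j = j, h = h, key = pair_key)
        }
      }
    }
    left <- best$i; right <- best$j
    if (keys[right] < keys[left]) { tmp <- left; left <- right; right <- tmp }
    merged <- c(clusters[[left]], clusters[[right]])
    merges[[length(merges) + 1L]] <- list(
      members = sort(labels[merged]), height = best$h)
    keep <- setdiff(seq_len(length(clusters)), c(best$i, best$j))
    clusters <- c(clusters[keep], list(merged))
    keys <- c(keys[keep], min(keys[c(left, right)]))
  }
  list(order = labels[clusters[[1]]], merges = merges)
}

#' @export
print.jaccard_result <- function(x, ...) {
  cat("Jaccard concordance (", x$direction, " lists), ",
      nrow(x$matrix), " comparisons\n", sep = "")
  cat("Leaf order:", paste(x$linkage_order, collapse = ", "), "\n")
  invisible(x)
}

#' Heatmap of a Jaccard concordance matrix
#'
#' @param x a `jaccard_result`.
#' @param ... passed to [graphics::image()].
#' @export
plot.jaccard_result <- function(x, ...) {
  ord <- match(x$linkage_order, rownames(x$matrix))
  m <- x$matrix[ord, ord]
  pal <- grDevices::hcl.colors(51, "YlOrRd", rev = TRUE)
  graphics::image(x = seq_len(ncol(m)), y = seq_len(nrow(m)),
                  z = t(m[rev(seq_len(nrow(m))), , drop = FALSE]),
                  col = pal, zlim = c(0, 1), axes = FALSE,
                  xlab = "", ylab = "", ...)
  graphics::axis(1, at = seq_len(ncol(m)), labels = colnames(m), las = 2,
                 cex.axis = 0.7)
  graphics::axis(2, at = seq_len(nrow(m)), labels = rev(rownames(m)), las = 2,
                 cex.axis = 0.7)
  graphics::box()
  invisible(x)
}

#' Translate platform probe ids to gene names and collapse duplicates
#'
#' Probe/array ids are translated through a two-column map; rows without a
#' match are discarded (count reported), and duplicate gene names are
#' collapsed by keeping the row with the highest total counts.
#'
#' @param counts probes x samples count matrix (probe ids as rownames).
#' @param platform_map data.frame: first column probe id, second gene name.
#' @return count matrix re-keyed to gene names.
#' @export
harmonize_ids <- function(counts, platform_map) {
  counts <- check_counts(counts)
  if (!is.data.frame(platform_map) || ncol(platform_map) < 2L ||
      nrow(platform_map) == 0L) {
    stop("platform map must be a non-empty two-column table", call. = FALSE)
  }
  probe <- as.character(platform_map[[1]])
  gene <- as.character(platform_map[[2]])
  hit <- match(rownames(counts), probe)
  kept <- !is.na(hit) & !is.na(gene[hit]) & nzchar(gene[hit])
  n_drop <- sum(!kept)
  if (n_drop) message("harmonize_ids: discarded ", n_drop,
                      " unmatched probe(s)")
  if (!any(kept)) stop("no probes could be translated", call. = FALSE)
  out <- counts[kept, , drop = FALSE]
  gn <- gene[hit[kept]]
  totals <- rowSums(out)
  # keep, per gene name, the probe with the highest total counts
  ord <- order(gn, -totals, rownames(out))
  out <- out[ord, , drop = FALSE]
  gn <- gn[ord]
  first <- !duplicated(gn)
  out <- out[first, , drop = FALSE]
  rownames(out) <- gn[first]
  out
}
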