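# Readers and writers for the plain-text formats the pipeline touches:
# Matrix Market sparse counts with genes.tsv / barcodes.tsv sidecars, and
# tab-separated tables. All writers are deterministic byte-for-byte.

#' Write a count matrix as Matrix Market with gene/barcode sidecars
#'
#' @param counts genes x columns count matrix.
#' @param dir output directory (created if needed); files `matrix.mtx`,
#'   `genes.tsv`, `barcodes.tsv`.
#' @return the directory, invisibly.
#' @export
write_counts_mtx <- function(counts, dir) {
  counts <- check_counts(counts)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  m <- Matrix::Matrix(counts, sparse = TRUE)
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read a Matrix Market count matrix with gene/barcode sidecars
#'
#' @param dir directory holding `matrix.mtx`, `genes.tsv`, `barcodes.tsv`.
#' @return dense integer matrix, genes x columns.
#' @export
read_counts_mtx <- function(dir) {
  paths <- file.path(dir, c("matrix.mtx", "genes.tsv", "barcodes.tsv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("missing input file(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(Matrix::readMM(paths[1]))
  genes <- readLines(paths[2])
  # 10x-style sidecars may carry extra columns (id\tsymbol); keep column 1.
  genes <- vapply(strsplit(genes, "\t", fixed = TRUE), `[`, "", 1L)
  cells <- readLines(paths[3])
  if (nrow(m) != length(genes) || ncol(m) != length(cells)) {
    stop("matrix dimensions do not match genes/barcodes sidecars", call. = FALSE)
  }
  dimnames(m) <- list(genes, cells)
  storage.mode(m) <- "integer"
  m
}

#' Write a genes x samples count table as TSV
#'
#' First column `gene_id`, one column per sample.
#' @param counts genes x samples matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_counts_tsv <- function(counts, path) {
  counts <- check_counts(counts)
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read a genes x samples count table from TSV
#'
#' @param path TSV with a `gene_id` first column.
#' @return numeric matrix with gene ids as rownames.
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"gene_id" %in% names(df)) {
    stop("count table must have a 'gene_id' column: ", path, call. = FALSE)
  }
  m <- as.matrix(df[, setdiff(names(df), "gene_id"), drop = FALSE])
  rownames(m) <- df$gene_id
  storage.mode(m) <- "double"
  m
}

# Deterministic TSV writer used throughout the package.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Write a full synthetic bundle to disk
#'
#' Lays out the simulated single-cell counts (MTX + sidecars), cell
#' metadata, bulk query counts and sample metadata, orthologue map,
#' severity table and a ground-truth manifest as plain-text files — the
#' same formats the pipeline reads back.
#'
#' @param sim result of [simulate_timecourse()].
#' @param bulk result of [simulate_query_bulk()].
#' @param ortho_map data.frame from [make_orthologue_map()] (or NULL).
#' @param severity data.frame from [simulate_severity()] (or NULL).
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_sim_bundle <- function(sim, bulk, ortho_map = NULL, severity = NULL,
                             dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_counts_mtx(sim$counts, file.path(dir, "sc_counts"))
  write_tsv(sim$meta, file.path(dir, "cell_metadata.tsv"))
  write_counts_tsv(bulk$counts, file.path(dir, "query_counts.tsv"))
  write_tsv(bulk$meta, file.path(dir, "sample_metadata.tsv"))
  if (!is.null(ortho_map)) write_tsv(ortho_map, file.path(dir, "orthologues.tsv"))
  if (!is.null(severity)) write_tsv(severity, file.path(dir, "severity.tsv"))
  truth_rows <- do.call(rbind, lapply(names(sim$truth$signature_genes), function(tp) {
    g <- sim$truth$signature_genes[[tp]]
    if (!length(g)) return(NULL)
    data.frame(timepoint_hr = tp, gene_id = g, stringsAsFactors = FALSE)
  }))
  if (!is.null(truth_rows)) write_tsv(truth_rows, file.path(dir, "truth_signatures.tsv"))
  invisible(dir)
}
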