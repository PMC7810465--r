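#' Published per-time-point recovered cell counts
#'
#' The number of cells recovered at each of the seven time points (0, 1, 4,
#' 16, 27, 36, 48 hr post-LPS) in the murine endotoxemia scRNA-seq time
#' course (GEO GSE151658): 9191, 9460, 9865, 5165, 7678, 10119 and 11809
#' cells, 63,287 in total. Shipped as a plain-text table; useful as the
#' realistic size reference for simulations and for consistency checks.
#'
#' @return data.frame with columns `timepoint_hr` and `n_cells`.
#' @examples
#' sum(recovered_cell_counts()$n_cells)
#' @export
recovered_cell_counts <- function() {
  read_tsv(system.file("extdata", "recovered_cell_counts.tsv",
                       package = "sepstager", mustWork = TRUE))
}
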