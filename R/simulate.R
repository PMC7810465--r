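#' Configuration for the synthetic endotoxemia time course
#'
#' Bundles and validates the parameters of the gamma-Poisson (negative
#' binomial) single-cell simulator. Defaults describe the standard desk-scale
#' study: seven time points spanning 0-48 hr after LPS, 300 cells per time
#' point, 2000 genes, 40 disjoint signature genes per time point planted at
#' log2 fold change 3, NB dispersion 0.1.
#'
#' @param n_genes number of genes in the simulated universe.
#' @param n_cells_per_timepoint cells drawn at each time point.
#' @param timepoints strictly increasing vector of hours post-LPS.
#' @param n_signature_genes_per_timepoint disjoint planted marker genes per
#'   time point (`n_genes` must accommodate all of them plus the mito genes).
#' @param signature_log2fc planted log2 fold change of a time point's
#'   signature genes in its own cells relative to all other cells (>= 0).
#' @param nb_dispersion negative-binomial dispersion phi (> 0); variance of a
#'   count with mean mu is mu + phi * mu^2.
#' @param mean_library_size expected total UMI count per cell.
#' @param library_size_sdlog log-normal sd of per-cell library sizes.
#' @param mito_fraction_range interval in \[0,1\]: each cell's expected
#'   mitochondrial expression share is drawn uniformly from it.
#' @param n_mito_genes genes named with the `mt-` prefix carrying the
#'   mitochondrial share.
#' @param seed integer seed; identical seeds give bit-identical simulations.
#' @return an object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_genes = 300, n_cells_per_timepoint = 50, seed = 1)
#' @export
sim_config <- function(n_genes = 2000,
                       n_cells_per_timepoint = 300,
                       timepoints = c(0, 1, 4, 16, 27, 36, 48),
                       n_signature_genes_per_timepoint = 40,
                       signature_log2fc = 3,
                       nb_dispersion = 0.1,
                       mean_library_size = 5000,
                       library_size_sdlog = 0.3,
                       mito_fraction_range = c(0.01, 0.20),
                       n_mito_genes = 10,
                       seed = 999) {
  check_scalar(n_genes, "n_genes", lower = 1, integer = TRUE)
  check_scalar(n_cells_per_timepoint, "n_cells_per_timepoint", lower = 1,
               integer = TRUE)
  if (!is.numeric(timepoints) || length(timepoints) < 2L ||
      any(diff(timepoints) <= 0)) {
    stop("'timepoints' must be a strictly increasing numeric vector", call. = FALSE)
  }
  check_scalar(n_signature_genes_per_timepoint, "n_signature_genes_per_timepoint",
               lower = 0, integer = TRUE)
  check_scalar(signature_log2fc, "signature_log2fc", lower = 0)
  check_scalar(nb_dispersion, "nb_dispersion", lower = 0, strict_lower = TRUE)
  check_scalar(mean_library_size, "mean_library_size", lower = 0,
               strict_lower = TRUE)
  check_scalar(library_size_sdlog, "library_size_sdlog", lower = 0)
  if (!is.numeric(mito_fraction_range) || length(mito_fraction_range) != 2L ||
      any(mito_fraction_range < 0) || any(mito_fraction_range > 1) ||
      mito_fraction_range[1] > mito_fraction_range[2]) {
    stop("'mito_fraction_range' must be an interval within [0, 1]", call. = FALSE)
  }
  check_scalar(n_mito_genes, "n_mito_genes", lower = 0, integer = TRUE)
  needed <- n_signature_genes_per_timepoint * length(timepoints) + n_mito_genes
  if (n_genes < needed) {
    stop(sprintf("n_genes = %d cannot hold %d signature genes plus %d mito genes",
                 n_genes, needed - n_mito_genes, n_mito_genes), call. = FALSE)
  }
  structure(list(
    n_genes = as.integer(n_genes),
    n_cells_per_timepoint = as.integer(n_cells_per_timepoint),
    timepoints = as.numeric(timepoints),
    n_signature_genes_per_timepoint = as.integer(n_signature_genes_per_timepoint),
    signature_log2fc = signature_log2fc,
    nb_dispersion = nb_dispersion,
    mean_library_size = mean_library_size,
    library_size_sdlog = library_size_sdlog,
    mito_fraction_range = mito_fraction_range,
    n_mito_genes = as.integer(n_mito_genes),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate a single-cell endotoxemia time course
#'
#' Draws a genes x cells count matrix from a gamma-Poisson model: gene
#' baseline expression shares are log-normal, per-cell library sizes are
#' log-normal, and each time point carries a disjoint set of planted
#' signature genes whose expected expression is multiplied by
#' `2^signature_log2fc` in that time point's cells (expression shares are
#' renormalized per cell, so the planted program also induces the mild
#' compositional shift that between-sample normalization must absorb).
#' Mitochondrial genes (`mt-` prefix) carry a per-cell share drawn uniformly
#' from `mito_fraction_range`, so QC covariates are consistent with the
#' matrix itself.
#'
#' @param config a [sim_config()] object.
#' @return a list with components
#'   \describe{
#'     \item{counts}{integer matrix, genes x cells, with gene/cell ids.}
#'     \item{meta}{data.frame of per-cell metadata: `cell_id`,
#'       `timepoint_hr`, `cell_type`, `n_genes_detected`, `mito_percent`.}
#'     \item{truth}{ground-truth list: `signature_genes` (per time point),
#'       `programs` (genes x time points expected expression shares),
#'       `timepoints`, and the generating `config`.}
#'   }
#' @examples
#' sim <- simulate_timecourse(sim_config(n_genes = 300,
#'                                       n_cells_per_timepoint = 40, seed = 7))
#' dim(sim$counts)
#' @export
simulate_timecourse <- function(config) {
  if (!inherits(config, "sim_config")) {
    stop("'config' must be created by sim_config()", call. = FALSE)
  }
  with_seed(config$seed, {
    G <- config$n_genes
    tps <- config$timepoints
    Tn <- length(tps)
    nc <- config$n_cells_per_timepoint
    K <- config$n_signature_genes_per_timepoint

    gene_ids <- sprintf("mgene%05d", seq_len(G))
    mito_idx <- integer(0)
    if (config$n_mito_genes > 0L) {
      mito_idx <- seq_len(config$n_mito_genes)
      gene_ids[mito_idx] <- sprintf("mt-gene%02d", seq_len(config$n_mito_genes))
    }

    # Baseline expression shares, log-normal across genes.
    base <- stats::rlnorm(G, meanlog = 0, sdlog = 1)

    # Disjoint planted signatures among the non-mito genes.
    candidates <- setdiff(seq_len(G), mito_idx)
    sig_idx <- vector("list", Tn)
    if (K > 0L) {
      picked <- sample(candidates, K * Tn, replace = FALSE)
      sig_idx <- split(picked, rep(seq_len(Tn), each = K))
    } else {
      sig_idx <- replicate(Tn, integer(0), simplify = FALSE)
    }
    names(sig_idx) <- as.character(tps)

    # Per-time-point expected expression shares (renormalized to sum 1).
    effect <- 2^config$signature_log2fc
    programs <- matrix(base, nrow = G, ncol = Tn,
                       dimnames = list(gene_ids, as.character(tps)))
    for (j in seq_len(Tn)) {
      programs[sig_idx[[j]], j] <- programs[sig_idx[[j]], j] * effect
    }
    programs <- sweep(programs, 2, colSums(programs), "/")

    n_cells <- nc * Tn
    cell_ids <- sprintf("cell_t%s_%04d", rep(as.character(tps), each = nc),
                        rep(seq_len(nc), Tn))
    lib <- stats::rlnorm(n_cells,
                         meanlog = log(config$mean_library_size) -
                           config$library_size_sdlog^2 / 2,
                         sdlog = config$library_size_sdlog)
    mito_share <- stats::runif(n_cells, config$mito_fraction_range[1],
                               config$mito_fraction_range[2])

    counts <- matrix(0L, nrow = G, ncol = n_cells,
                     dimnames = list(gene_ids, cell_ids))
    size <- 1 / config$nb_dispersion
    for (j in seq_len(Tn)) {
      cols <- (j - 1L) * nc + seq_len(nc)
      p <- programs[, j]
      if (length(mito_idx)) {
        p_mito <- p[mito_idx] / sum(p[mito_idx])
        p_rest <- p
        p_rest[mito_idx] <- 0
        p_rest <- p_rest / sum(p_rest)
        # cell-specific mixture of mito and nuclear shares
        mu <- p_rest %o% ((1 - mito_share[cols]) * lib[cols]) +
          (replace(numeric(G), mito_idx, p_mito)) %o% (mito_share[cols] * lib[cols])
      } else {
        mu <- p %o% lib[cols]
      }
      counts[, cols] <- stats::rnbinom(length(mu), size = size, mu = mu)
    }
    storage.mode(counts) <- "integer"

    cell_type <- sample(c("PT", "TAL", "DCT", "EC", "immune"), n_cells,
                        replace = TRUE, prob = c(0.4, 0.2, 0.1, 0.15, 0.15))
    tot <- colSums(counts)
    mito_pct <- if (length(mito_idx)) {
      100 * colSums(counts[mito_idx, , drop = FALSE]) / pmax(tot, 1)
    } else rep(0, n_cells)

    meta <- data.frame(
      cell_id = cell_ids,
      timepoint_hr = rep(tps, each = nc),
      cell_type = cell_type,
      n_genes_detected = colSums(counts > 0L),
      mito_percent = mito_pct,
      stringsAsFactors = FALSE
    )
    rownames(meta) <- NULL

    truth <- structure(list(
      signature_genes = lapply(sig_idx, function(i) gene_ids[i]),
      programs = programs,
      timepoints = tps,
      config = config
    ), class = "sim_truth")

    list(counts = counts, meta = meta, truth = truth)
  })
}

#' Simulate bulk query and reference samples from the time-course programs
#'
#' Query samples are independent bulk libraries (not pseudobulks): each is
#' drawn from its true stage's expected expression program, translated to the
#' "human" gene universe through an orthologue map, with per-gene
#' multiplicative log-normal noise of sd `noise_sd` and Poisson counting
#' noise. Reference samples are drawn the same way from the baseline
#' (earliest time point) program — they emulate unaffected control tissue.
#' By default query stages are the non-baseline time points: a query drawn
#' from the baseline program is indistinguishable from the references by
#' construction (its fold-change vector versus the reference mean is
#' identically zero), so it is not a recoverable staging case.
#'
#' @param truth the `truth` component returned by [simulate_timecourse()].
#' @param n_queries_per_stage query samples per simulated stage.
#' @param n_references reference samples (>= 2).
#' @param noise_sd sd of the per-gene log-normal noise (>= 0).
#' @param seed integer seed.
#' @param ortho_map optional orthologue map (data.frame `mouse`, `human`),
#'   e.g. from [make_orthologue_map()]; it is resolved to its one-to-one
#'   pairs and queries are generated on the mapped human gene universe.
#'   `NULL` keeps the mouse gene ids.
#' @param query_stages time points to draw query stages from; default all
#'   but the earliest.
#' @param mean_library_size expected bulk library size.
#' @return list with `counts` (genes x samples integer matrix) and `meta`
#'   (data.frame: `sample_id`, `is_reference`, `true_stage_hr`; reference
#'   samples have `NA` stage).
#' @export
simulate_query_bulk <- function(truth, n_queries_per_stage = 9,
                                n_references = 4, noise_sd = 0.2,
                                seed = 999, ortho_map = NULL,
                                query_stages = NULL,
                                mean_library_size = 1e6) {
  if (!inherits(truth, "sim_truth")) {
    stop("'truth' must be the truth component of simulate_timecourse()",
         call. = FALSE)
  }
  check_scalar(n_queries_per_stage, "n_queries_per_stage", lower = 0,
               integer = TRUE)
  check_scalar(n_references, "n_references", lower = 2, integer = TRUE)
  check_scalar(noise_sd, "noise_sd", lower = 0)
  tps <- truth$timepoints
  query_stages <- query_stages %||% tps[-1]
  if (!all(query_stages %in% tps)) {
    stop("'query_stages' must be simulated time points", call. = FALSE)
  }

  programs <- truth$programs
  if (!is.null(ortho_map)) {
    map <- resolve_orthologues(ortho_map)
    keep <- rownames(programs) %in% map$mouse
    if (!any(keep)) stop("orthologue map shares no genes with the simulation",
                         call. = FALSE)
    programs <- programs[keep, , drop = FALSE]
    rownames(programs) <- map$human[match(rownames(programs), map$mouse)]
    programs <- sweep(programs, 2, colSums(programs), "/")
  }

  with_seed(seed, {
    G <- nrow(programs)
    stage_of <- c(rep(tps[1], n_references),
                  rep(query_stages, each = n_queries_per_stage))
    ids <- c(sprintf("ref_%02d", seq_len(n_references)),
             if (n_queries_per_stage > 0)
               sprintf("query_t%s_%02d",
                       rep(as.character(query_stages), each = n_queries_per_stage),
                       rep(seq_len(n_queries_per_stage), length(query_stages))))
    n <- length(ids)
    counts <- matrix(0L, nrow = G, ncol = n,
                     dimnames = list(rownames(programs), ids))
    for (i in seq_len(n)) {
      p <- programs[, as.character(stage_of[i])]
      if (noise_sd > 0) p <- p * exp(stats::rnorm(G, 0, noise_sd))
      mu <- p / sum(p) * mean_library_size
      counts[, i] <- stats::rpois(G, mu)
    }
    storage.mode(counts) <- "integer"
    meta <- data.frame(
      sample_id = ids,
      is_reference = c(rep(TRUE, n_references), rep(FALSE, n - n_references)),
      true_stage_hr = ifelse(seq_len(n) <= n_references, NA_real_, stage_of),
      stringsAsFactors = FALSE
    )
    list(counts = counts, meta = meta)
  })
}

#' Simulate a mouse-to-human orthologue map with realistic pathologies
#'
#' Emits mouse-to-human gene pairs with a controllable mixture of clean
#' one-to-one pairs, unmapped mouse genes, and one-to-many cases (one mouse
#' gene paired with two human genes), which exercises the collision handling
#' of the staging translation step.
#'
#' @param genes mouse gene ids to map.
#' @param frac_one_to_one fraction mapped one-to-one.
#' @param frac_unmapped fraction absent from the map.
#' @param seed integer seed.
#' @return data.frame with columns `mouse` and `human`, one row per pair.
#' @examples
#' make_orthologue_map(c("a", "b", "c", "d"), 0.5, 0.25, seed = 1)
#' @export
make_orthologue_map <- function(genes, frac_one_to_one = 0.8,
                                frac_unmapped = 0.1, seed = 999) {
  if (!is.character(genes) || anyDuplicated(genes)) {
    stop("'genes' must be unique gene ids", call. = FALSE)
  }
  check_scalar(frac_one_to_one, "frac_one_to_one", lower = 0, upper = 1)
  check_scalar(frac_unmapped, "frac_unmapped", lower = 0, upper = 1)
  if (frac_one_to_one + frac_unmapped > 1 + 1e-12) {
    stop("frac_one_to_one + frac_unmapped must be <= 1", call. = FALSE)
  }
  with_seed(seed, {
    n <- length(genes)
    shuffled <- sample(genes)
    n_un <- round(frac_unmapped * n)
    n_11 <- round(frac_one_to_one * n)
    n_11 <- min(n_11, n - n_un)
    unmapped <- shuffled[seq_len(n_un)]
    one2one <- shuffled[n_un + seq_len(n_11)]
    multi <- setdiff(shuffled, c(unmapped, one2one))
    human_of <- function(g) {
      if (!length(g)) return(character(0))
      paste0("H-", toupper(g))
    }
    rows <- list(data.frame(mouse = one2one, human = human_of(one2one),
                            stringsAsFactors = FALSE))
    if (length(multi)) {
      rows <- c(rows, list(
        data.frame(mouse = rep(multi, each = 2),
                   human = as.vector(rbind(human_of(multi),
                                           paste0(human_of(multi), "-B"))),
                   stringsAsFactors = FALSE)))
    }
    out <- do.call(rbind, rows)
    out <- out[order(out$mouse, out$human), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Simulate SOFA-like severity scores with a planted stage relationship
#'
#' Scores follow `round(intercept + slope * stage_rank + noise)` clamped to
#' the SOFA range \[0, 24\], where `stage_rank` is the 1-based rank of a
#' sample's stage among the distinct stages present. A negative slope plants
#' the clinical pattern in which samples matching later (recovery) time
#' points carry lower severity.
#'
#' @param assignments named numeric vector: sample id -> stage (hours).
#' @param slope severity change per stage rank.
#' @param noise_sd sd of the Gaussian noise added before rounding.
#' @param seed integer seed.
#' @param intercept baseline severity at rank 0 (default 20).
#' @return data.frame with columns `sample_id` and `sofa` (integer, 0-24).
#' @export
simulate_severity <- function(assignments, slope, noise_sd = 1, seed = 999,
                              intercept = 20) {
  if (is.null(names(assignments)) || !is.numeric(assignments)) {
    stop("'assignments' must be a named numeric vector (sample -> stage)",
         call. = FALSE)
  }
  check_scalar(noise_sd, "noise_sd", lower = 0)
  stages <- sort(unique(assignments))
  rank_of <- match(assignments, stages)
  with_seed(seed, {
    raw <- intercept + slope * rank_of + stats::rnorm(length(assignments), 0, noise_sd)
    sofa <- as.integer(pmin(24, pmax(0, round(raw))))
    data.frame(sample_id = names(assignments), sofa = sofa,
               stringsAsFactors = FALSE)
  })
}
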