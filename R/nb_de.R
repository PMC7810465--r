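# Negative-binomial differential-expression engine: trimmed-mean (TMM)
# normalization factors, moment-based dispersion estimation with shrinkage,
# per-gene Wald tests (one-vs-rest or one-vs-one), and Benjamini-Hochberg
# FDR. The engine is self-contained and validated against independent
# brute-force oracles in the test suite.

#' TMM normalization factors
#'
#' Computes trimmed-mean-of-M-values scaling factors: for each column, the
#' precision-weighted mean of gene-wise log2 ratios against a reference
#' column, doubly trimmed on log-ratio (`trim_logratio` from each tail) and
#' on average abundance (`trim_abundance` from each tail), exponentiated and
#' rescaled so the factors have geometric mean 1. The reference column is
#' the one whose upper-quartile expression is closest to the mean upper
#' quartile. Effective library size = column sum x factor.
#'
#' @param counts genes x columns count matrix (>= 2 columns, no all-zero
#'   columns).
#' @param trim_logratio fraction trimmed from each tail of the log-ratios.
#' @param trim_abundance fraction trimmed from each tail of the abundances.
#' @param ref_column optional reference column index; default auto-chosen.
#' @return object of class `norm_factors`: list with `factors` (named,
#'   geometric mean 1), `lib_size`, and `effective_lib_size`.
#' @examples
#' pb <- matrix(rpois(400, 20), 100, 4,
#'              dimnames = list(paste0("g", 1:100), paste0("s", 1:4)))
#' tmm_factors(pb)$factors
#' @export
tmm_factors <- function(counts, trim_logratio = 0.3, trim_abundance = 0.05,
                        ref_column = NULL) {
  counts <- check_counts(counts)
  if (ncol(counts) < 2L) stop("TMM needs at least 2 columns", call. = FALSE)
  lib <- colSums(counts)
  if (any(lib == 0)) stop("all-zero column(s) present", call. = FALSE)
  check_scalar(trim_logratio, "trim_logratio", lower = 0, upper = 0.5)
  check_scalar(trim_abundance, "trim_abundance", lower = 0, upper = 0.5)

  f75 <- apply(sweep(counts, 2, lib, "/"), 2, stats::quantile, probs = 0.75)
  ref <- ref_column %||% which.min(abs(f75 - mean(f75)))

  factors <- vapply(seq_len(ncol(counts)), function(k) {
    tmm_pair_factor(counts[, k], counts[, ref], lib[k], lib[ref],
                    trim_logratio, trim_abundance)
  }, numeric(1))
  factors <- factors / exp(mean(log(factors)))
  names(factors) <- colnames(counts)
  structure(list(factors = factors, lib_size = lib,
                 effective_lib_size = lib * factors,
                 ref_column = ref),
            class = "norm_factors")
}

# One column's TMM factor against the reference column.
tmm_pair_factor <- function(obs, ref, n_obs, n_ref,
                            trim_logratio, trim_abundance) {
  logR <- log2((obs / n_obs) / (ref / n_ref))
  absE <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  # asymptotic (delta-method) variance of the log-ratio: the weights
  v <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  fin <- is.finite(logR) & is.finite(absE)
  logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
  if (!length(logR) || max(abs(logR)) < 1e-6) return(1)
  n <- length(logR)
  loL <- floor(n * trim_logratio) + 1
  hiL <- n + 1 - loL
  loS <- floor(n * trim_abundance) + 1
  hiS <- n + 1 - loS
  keep <- rank(logR) >= loL & rank(logR) <= hiL &
    rank(absE) >= loS & rank(absE) <= hiS
  if (!any(keep)) {
    stop("all genes trimmed away; use smaller trim fractions", call. = FALSE)
  }
  f <- sum(logR[keep] / v[keep], na.rm = TRUE) / sum(1 / v[keep], na.rm = TRUE)
  if (is.na(f)) f <- 0
  2^f
}

#' Moment-based NB dispersion estimation with shrinkage
#'
#' Per-gene dispersions by the method of moments on depth-adjusted counts:
#' counts are rescaled to a common effective library size, and within each
#' group with replicates the excess of the sample variance over the
#' depth-corrected Poisson expectation is converted to a dispersion
#' (`var = mu + phi * mu^2`). Gene-wise estimates are pooled across groups
#' (weighted by residual df), and shrunk toward the common (trimmed-mean)
#' dispersion: `tagwise = (1 - w) * max(raw, 0) + w * common`. The common
#' value is the trimmed mean of the raw (unfloored) estimates, floored at 0,
#' so that Poisson-distributed data yields a near-zero common dispersion.
#'
#' @param counts genes x columns count matrix.
#' @param groups column grouping vector (length = ncol).
#' @param norm `norm_factors` from [tmm_factors()]; `NULL` uses raw library
#'   sizes.
#' @param shrinkage_weight weight `w` in \[0,1\] of the common value.
#' @param fallback_dispersion used (with a warning) when no group has >= 2
#'   replicates.
#' @param trim trim fraction for the common (mean) dispersion.
#' @return object of class `dispersion_estimate`: list with `common`,
#'   `tagwise` (named per gene), `shrinkage_weight`.
#' @export
estimate_dispersion <- function(counts, groups, norm = NULL,
                                shrinkage_weight = 0.3,
                                fallback_dispersion = 0.1, trim = 0.1) {
  counts <- check_counts(counts)
  if (length(groups) != ncol(counts)) {
    stop("'groups' must have one entry per column", call. = FALSE)
  }
  check_scalar(shrinkage_weight, "shrinkage_weight", lower = 0, upper = 1)
  eff <- if (is.null(norm)) colSums(counts) else norm$effective_lib_size
  groups <- as.character(groups)
  tab <- table(groups)
  rep_groups <- names(tab)[tab >= 2L]
  gene_ids <- rownames(counts)

  if (!length(rep_groups)) {
    warning("no group has >= 2 replicates; using fallback dispersion ",
            fallback_dispersion, call. = FALSE)
    return(structure(list(common = fallback_dispersion,
                          tagwise = stats::setNames(rep(fallback_dispersion,
                                                        nrow(counts)), gene_ids),
                          shrinkage_weight = shrinkage_weight),
                     class = "dispersion_estimate"))
  }

  l_bar <- mean(eff)
  num <- denom <- rep(0, nrow(counts))
  wsum <- 0
  for (g in rep_groups) {
    idx <- which(groups == g)
    scale_i <- l_bar / eff[idx]
    s <- sweep(counts[, idx, drop = FALSE], 2, scale_i, "*")
    m <- rowMeans(s)
    v <- row_vars(s)
    cbar <- mean(scale_i)
    w <- length(idx) - 1
    ok <- m > 0
    # (v - cbar * m) / m^2 estimates phi; pool numerators over groups
    num[ok] <- num[ok] + w * (v[ok] - cbar * m[ok]) / (m[ok]^2)
    denom[ok] <- denom[ok] + w
    wsum <- wsum + w
  }
  raw <- ifelse(denom > 0, num / pmax(denom, 1), NA_real_)
  common <- max(0, mean(raw[is.finite(raw)], trim = trim))
  floored <- pmax(raw, 0)
  floored[!is.finite(floored)] <- common
  tagwise <- (1 - shrinkage_weight) * floored + shrinkage_weight * common
  structure(list(common = common,
                 tagwise = stats::setNames(tagwise, gene_ids),
                 shrinkage_weight = shrinkage_weight),
            class = "dispersion_estimate")
}

#' Per-gene negative-binomial Wald test
#'
#' Fits, per gene, NB mean rates for a target group and its complement
#' (one-vs-rest) or a single other group (one-vs-one), with effective
#' library sizes as offsets, and tests the log-rate difference with a Wald
#' statistic whose variance follows `var(count) = mu + phi * mu^2`. The
#' log2 fold change uses a prior count of `prior_count` per
#' library-size-scaled column, so genes at zero stay finite. Genes with zero
#' counts everywhere are excluded from testing and reported with `p = 1`,
#' `log2fc = 0`.
#'
#' @param counts genes x columns count matrix.
#' @param groups column grouping vector.
#' @param target_group group whose fold change is reported (target vs
#'   rest/other).
#' @param norm `norm_factors`; `NULL` computes TMM factors internally.
#' @param disp `dispersion_estimate`; `NULL` estimates internally (falling
#'   back to `fallback_dispersion` without replicates).
#' @param other_group if supplied, a one-vs-one contrast against this group.
#' @param prior_count prior count per scaled column for the fold change.
#' @param fallback_dispersion dispersion used when none can be estimated.
#' @return data.frame: `gene_id`, `log2fc`, `p_value`, `fdr`, `mean_cpm`,
#'   ordered as the input genes.
#' @export
nb_test <- function(counts, groups, target_group, norm = NULL, disp = NULL,
                    other_group = NULL, prior_count = 0.5,
                    fallback_dispersion = 0.1) {
  counts <- check_counts(counts)
  if (length(groups) != ncol(counts)) {
    stop("'groups' must have one entry per column", call. = FALSE)
  }
  groups <- as.character(groups)
  if (!as.character(target_group) %in% groups) {
    stop("target group '", target_group, "' not present", call. = FALSE)
  }
  idx1 <- groups == as.character(target_group)
  if (is.null(other_group)) {
    idx0 <- !idx1
  } else {
    if (!as.character(other_group) %in% groups) {
      stop("other group '", other_group, "' not present", call. = FALSE)
    }
    idx0 <- groups == as.character(other_group)
  }
  if (!any(idx0)) stop("comparison group is empty", call. = FALSE)

  use <- idx1 | idx0
  if (is.null(norm)) {
    norm <- tmm_factors(counts[, use, drop = FALSE])
    eff <- numeric(length(groups))
    eff[use] <- norm$effective_lib_size
  } else {
    eff <- norm$effective_lib_size
  }
  if (is.null(disp)) {
    disp <- tryCatch(
      estimate_dispersion(counts[, use, drop = FALSE], groups[use],
                          norm = list(effective_lib_size = eff[use]),
                          fallback_dispersion = fallback_dispersion),
      warning = function(w) {
        structure(list(common = fallback_dispersion,
                       tagwise = stats::setNames(rep(fallback_dispersion,
                                                     nrow(counts)),
                                                 rownames(counts)),
                       shrinkage_weight = 1),
                  class = "dispersion_estimate")
      })
  }
  phi <- disp$tagwise[rownames(counts)]
  phi[!is.finite(phi)] <- disp$common

  y1 <- rowSums(counts[, idx1, drop = FALSE])
  y0 <- rowSums(counts[, idx0, drop = FALSE])
  l1 <- sum(eff[idx1]); l0 <- sum(eff[idx0])
  s1 <- sum(eff[idx1]^2); s0 <- sum(eff[idx0]^2)

  # prior is on the depth-normalized (counts-per-million) scale, i.e. 0.5
  # per library-size-scaled column, so fold changes stay finite at zeros
  # without attenuating well-measured genes
  cpm1 <- y1 / l1 * 1e6
  cpm0 <- y0 / l0 * 1e6
  log2fc <- log2((cpm1 + prior_count) / (cpm0 + prior_count))
  pr1 <- prior_count * l1 / 1e6
  pr0 <- prior_count * l0 / 1e6
  # Wald test on the unshrunk rates; the prior enters only where a group is
  # at zero (where the raw log-rate is undefined), keeping the statistic
  # unattenuated and the test calibrated for expressed genes.
  y1t <- ifelse(y1 > 0, y1, y1 + pr1)
  y0t <- ifelse(y0 > 0, y0, y0 + pr0)
  var_log <- 1 / y1t + phi * s1 / l1^2 + 1 / y0t + phi * s0 / l0^2
  z <- (log(y1t / l1) - log(y0t / l0)) / sqrt(var_log)
  p <- 2 * stats::pnorm(-abs(z))

  all_zero <- (y1 + y0) == 0
  log2fc[all_zero] <- 0
  p[all_zero] <- 1

  fdr <- rep(1, nrow(counts))
  tested <- !all_zero
  if (any(tested)) fdr[tested] <- bh_adjust(p[tested])

  data.frame(gene_id = rownames(counts),
             log2fc = log2fc,
             p_value = p,
             fdr = fdr,
             mean_cpm = (y1 + y0) / (l1 + l0) * 1e6,
             row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `adj_(i) = min_{j >= i} p_(j) * m / j`, clipped to 1, returned in the
#' input order.
#'
#' @param p_values p-values in \[0,1\].
#' @return adjusted values (FDR), same length and order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))
#' @export
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values)) stop("'p_values' must be numeric", call. = FALSE)
  if (!length(p_values)) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(p_values)
  o <- order(p_values, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p_values[o]))[ro]
}

#' Select significant genes at an FDR threshold
#'
#' Strict inequality: a gene at exactly `fdr == q` is excluded.
#'
#' @param results data.frame from [nb_test()].
#' @param q FDR threshold (default 0.05).
#' @return data.frame with `gene_id` and signed `log2fc` of the genes with
#'   `fdr < q`.
#' @export
significant_genes <- function(results, q = 0.05) {
  stopifnot(all(c("gene_id", "log2fc", "fdr") %in% names(results)))
  out <- results[results$fdr < q, c("gene_id", "log2fc"), drop = FALSE]
  rownames(out) <- NULL
  out
}
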