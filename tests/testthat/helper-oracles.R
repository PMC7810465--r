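# Independent brute-force oracles used to validate the package's own
# implementations, plus small shared fixtures. The oracles deliberately use
# explicit loops / closed forms and never call the code paths they check.

# mid-ranks by explicit counting (O(n^2))
oracle_midrank <- function(v) {
  vapply(v, function(a) sum(v < a) + (sum(v == a) + 1) / 2, numeric(1))
}

# Spearman rho as Pearson correlation of mid-ranks via explicit sums
oracle_spearman <- function(x, y) {
  rx <- oracle_midrank(x)
  ry <- oracle_midrank(y)
  n <- length(x)
  mx <- sum(rx) / n
  my <- sum(ry) / n
  num <- sum((rx - mx) * (ry - my))
  num / sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# Benjamini-Hochberg step-up by its definition: adj_(i) = min_{j>=i} p_(j)*m/j
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    cand <- vapply(i:m, function(j) p[o[j]] * m / j, numeric(1))
    adj[o[i]] <- min(1, min(cand))
  }
  adj
}

# Pairwise Jaccard matrix by explicit double loop over set pairs
oracle_jaccard_matrix <- function(sets) {
  n <- length(sets)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      a <- unique(sets[[i]]); b <- unique(sets[[j]])
      u <- length(unique(c(a, b)))
      m[i, j] <- if (u == 0) 1 else sum(a %in% b) / u
    }
  }
  m
}

# TMM factors by direct summation of the published doubly-trimmed,
# precision-weighted mean of gene-wise log ratios
oracle_tmm <- function(x, trimM = 0.3, trimA = 0.05) {
  lib <- colSums(x)
  uq <- vapply(seq_len(ncol(x)),
               function(i) unname(stats::quantile(x[, i] / lib[i], 0.75)),
               numeric(1))
  ref <- which.min(abs(uq - sum(uq) / length(uq)))
  f <- vapply(seq_len(ncol(x)), function(k) {
    o <- x[, k]; r <- x[, ref]
    keep <- o > 0 & r > 0
    o <- o[keep]; r <- r[keep]
    M <- log2((o / lib[k]) / (r / lib[ref]))
    A <- (log2(o / lib[k]) + log2(r / lib[ref])) / 2
    w <- 1 / ((lib[k] - o) / (lib[k] * o) + (lib[ref] - r) / (lib[ref] * r))
    if (length(M) == 0 || max(abs(M)) < 1e-6) return(1)
    n <- length(M)
    rM <- oracle_midrank(M); rA <- oracle_midrank(A)
    loM <- floor(n * trimM) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trimA) + 1; hiA <- n + 1 - loA
    keep2 <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    2^(sum(M[keep2] * w[keep2]) / sum(w[keep2]))
  }, numeric(1))
  f / exp(sum(log(f)) / length(f))
}

# Cophenetic distances implied by a merge history (list of members/height):
# the height of the first merge joining each pair.
cophenetic_from_merges <- function(merges, labels) {
  n <- length(labels)
  d <- matrix(NA_real_, n, n, dimnames = list(labels, labels))
  for (m in merges) {
    idx <- match(m$members, labels)
    for (i in idx) for (j in idx) {
      if (i != j && is.na(d[i, j])) d[i, j] <- d[j, i] <- m$height
    }
  }
  diag(d) <- 0
  d
}

# small deterministic NB count fixture
random_nb_counts <- function(n_genes, n_cols, seed, mu_sdlog = 1,
                             dispersion = 0.2, depth = 30) {
  set.seed(seed)
  mu <- exp(rnorm(n_genes, log(depth / n_genes * 100), mu_sdlog))
  x <- matrix(rnbinom(n_genes * n_cols, mu = mu, size = 1 / dispersion),
              n_genes, n_cols,
              dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_cols))))
  x[rowSums(x) > 0, , drop = FALSE]
}

# small end-to-end synthetic bundle shared by staging/pipeline tests
small_config <- function(seed = 11, log2fc = 3) {
  sim_config(n_genes = 600, n_cells_per_timepoint = 80,
             n_signature_genes_per_timepoint = 20,
             signature_log2fc = log2fc, nb_dispersion = 0.1,
             mean_library_size = 3000, seed = seed)
}
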