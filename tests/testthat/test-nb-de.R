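test_that("TMM factors are symmetric and depth-invariant", {
  x <- random_nb_counts(300, 2, seed = 1)
  same <- cbind(a = x[, 1], b = x[, 1])
  rownames(same) <- rownames(x)
  expect_equal(unname(tmm_factors(same)$factors), c(1, 1))
  dbl <- cbind(a = x[, 1], b = 2L * x[, 1])
  rownames(dbl) <- rownames(x)
  expect_equal(unname(tmm_factors(dbl)$factors), c(1, 1))
})

test_that("TMM factors match the brute-force and edgeR oracles", {
  skip_if_not_installed("edgeR")
  for (s in 1:25) {
    x <- random_nb_counts(250, sample(3:6, 1), seed = s)
    f <- tmm_factors(x)$factors
    expect_equal(unname(f), unname(oracle_tmm(x)), tolerance = 1e-6)
    expect_equal(unname(f),
                 unname(edgeR::calcNormFactors(x, method = "TMM")),
                 tolerance = 1e-6)
    expect_lt(abs(exp(mean(log(f))) - 1), 1e-9)
    # invariant under global rescaling of all columns
    f2 <- tmm_factors(x * 3L)$factors
    expect_equal(f, f2, tolerance = 1e-9)
  }
})

test_that("dispersion estimation recovers known truth and falls back sanely", {
  # Poisson truth: common estimate near zero
  set.seed(10)
  mu <- exp(rnorm(1000, 1, 1))
  x <- matrix(rpois(1000 * 200, mu), 1000, 200,
              dimnames = list(sprintf("g%04d", 1:1000),
                              sprintf("c%03d", 1:200)))
  grp <- rep(c("a", "b"), each = 100)
  d0 <- estimate_dispersion(x, grp)
  expect_lte(d0$common, 0.02)
  # NB truth 0.5
  x5 <- matrix(rnbinom(1000 * 200, mu = mu, size = 2), 1000, 200,
               dimnames = dimnames(x))
  d5 <- estimate_dispersion(x5, grp)
  expect_gte(d5$common, 0.35)
  expect_lte(d5$common, 0.65)
  expect_true(all(d5$tagwise >= 0))
  # single column per group -> fallback with warning
  y <- x[, 1:2]
  expect_warning(df <- estimate_dispersion(y, c("a", "b"),
                                           fallback_dispersion = 0.1),
                 "fallback")
  expect_equal(df$common, 0.1)
})

test_that("nb_test recovers planted fold changes and honors contracts", {
  # true 8-fold rate increase, dispersion 0.1, 300 vs 1800 cells
  set.seed(21)
  n_genes <- 400
  mu <- exp(rnorm(n_genes, 0.5, 1))
  up <- 1:20
  mk <- function(n, boost) {
    m <- matrix(mu, n_genes, n)
    m[up, ] <- m[up, ] * boost
    matrix(rnbinom(length(m), mu = m, size = 10), n_genes, n)
  }
  counts <- cbind(mk(300, 8), mk(1800, 1))
  dimnames(counts) <- list(sprintf("g%03d", 1:n_genes),
                           sprintf("c%04d", 1:2100))
  grp <- rep(c("t", "rest"), c(300, 1800))
  res <- nb_test(counts, grp, "t")
  expect_equal(mean(res$log2fc[up]), 3, tolerance = 0.3)
  expect_true(all(res$fdr[up] < 0.05))
  # null genes: TMM absorbs most of the heavy compositional shift the
  # planted block induces (~30% of library mass), leaving a small residual
  # bias and tight spread
  expect_lt(abs(mean(res$log2fc[-up])), 0.15)
  expect_lt(sd(res$log2fc[-up]), 0.15)
  # all-zero gene contract
  z <- counts; z[5, ] <- 0L
  resz <- nb_test(z, grp, "t")
  expect_equal(resz$p_value[5], 1)
  expect_equal(resz$log2fc[5], 0)
})

test_that("nb_test p-values are near-uniform under the null", {
  set.seed(33)
  mu <- exp(rnorm(800, 1, 1))
  counts <- matrix(rnbinom(800 * 500, mu = mu, size = 10), 800, 500,
                   dimnames = list(sprintf("g%03d", 1:800),
                                   sprintf("c%03d", 1:500)))
  grp <- rep(c("a", "b"), c(150, 350))
  res <- nb_test(counts, grp, "a")
  expect_gt(mean(res$p_value < 0.05), 0.02)
  expect_lt(mean(res$p_value < 0.05), 0.08)
  expect_lt(mean(abs(res$log2fc)), 0.12)
})

test_that("bh_adjust equals the step-up definition and stats::p.adjust", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.4), 0.4)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(99)
  for (i in 1:200) {
    p <- runif(sample(1:12, 1))
    if (i %% 3 == 0) p[sample(length(p), 1)] <- p[1]  # inject ties
    a <- bh_adjust(p)
    expect_equal(a, oracle_bh(p), tolerance = 1e-12)
    expect_equal(a, stats::p.adjust(p, method = "BH"), tolerance = 1e-12)
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, -0.1)), "\\[0, 1\\]")
})

test_that("significant_genes uses a strict FDR threshold", {
  res <- data.frame(gene_id = c("a", "b", "c"),
                    log2fc = c(2, -1, 0.5),
                    p_value = c(0.001, 0.01, 0.04),
                    fdr = c(0.003, 0.05, 0.049))
  sig <- significant_genes(res, q = 0.05)
  expect_setequal(sig$gene_id, c("a", "c"))   # fdr == 0.05 excluded
  expect_equal(sig$log2fc[sig$gene_id == "b"], numeric(0))
  expect_equal(nrow(significant_genes(res[0, ], 0.05)), 0)
})
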