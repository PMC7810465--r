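mk_sig <- function(tp, lfc) {
  structure(list(timepoint_hr = tp, genes = names(lfc), log2fc = lfc),
            class = "timepoint_signature")
}

test_that("spearman_rho matches closed forms and the brute-force oracle", {
  x <- c(3, 1, 4, 1.5, 9)
  expect_equal(spearman_rho(x, x), 1)
  expect_equal(spearman_rho(c(1, 2, 3, 5), c(5, 3, 2, 1)), -1)
  expect_equal(spearman_rho(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)  # 1 - 6*2/60
  set.seed(7)
  for (i in 1:100) {
    n <- sample(3:30, 1)
    a <- sample(1:8, n, replace = TRUE)   # ties likely
    b <- rnorm(n)
    if (length(unique(a)) < 2) a[1] <- a[1] + 1
    expect_equal(spearman_rho(a, b), oracle_spearman(a, b), tolerance = 1e-12)
    expect_equal(spearman_rho(a, b),
                 suppressWarnings(stats::cor(a, b, method = "spearman")),
                 tolerance = 1e-12)
  }
  # invariance under strictly monotone transforms
  a <- rnorm(20); b <- rnorm(20)
  expect_equal(spearman_rho(exp(a), b), spearman_rho(a, b))
  expect_equal(spearman_rho(a, 3 * b - 7), spearman_rho(a, b))
  expect_warning(r <- spearman_rho(rep(1, 5), rnorm(5)), "constant")
  expect_true(is.nan(r))
})

test_that("orthologue resolution and signature translation behave", {
  map <- data.frame(mouse = c("m1", "m2", "m2", "m3", "m4", "m5"),
                    human = c("H1", "H2a", "H2b", "H3", "H4", "H4x"))
  res <- suppressMessages(resolve_orthologues(map))
  expect_setequal(res$mouse, c("m1", "m3", "m4", "m5"))
  sig <- mk_sig(16, stats::setNames(c(1.5, -2, 0.5, 3), paste0("m", 1:4)))
  tr <- suppressMessages(translate_signature(sig, map))
  expect_setequal(tr$genes, c("H1", "H3", "H4"))     # m2 ambiguous -> dropped
  expect_equal(unname(tr$log2fc["H3"]), 0.5)         # fold change carried over
  # bijective map preserves the gene count
  bij <- data.frame(mouse = paste0("m", 1:4), human = paste0("B", 1:4))
  expect_equal(length(translate_signature(sig, bij)$genes), 4)
  # map covering half the genes halves the signature
  half <- bij[1:2, ]
  expect_message(trh <- translate_signature(sig, half), "2 gene")
  expect_equal(length(trh$genes), 2)
})

test_that("query fold changes follow their closed form", {
  genes <- sprintf("g%02d", 1:20)
  ref <- matrix(rep(c(100L, 300L), c(10, 10)), 20, 2,
                dimnames = list(genes, c("r1", "r2")))
  q <- ref[, 1, drop = FALSE] * 2L   # same composition, double depth
  colnames(q) <- "q1"
  fc <- query_foldchange(cbind(ref, q), c("r1", "r2"))
  expect_equal(unname(fc$q1$log2fc), rep(0, 20), tolerance = 1e-9)
  # one gene doubled: that gene near 1, others near 0
  q2 <- ref[, 1, drop = FALSE]
  q2[1, 1] <- q2[1, 1] * 2L
  colnames(q2) <- "q2"
  fc2 <- query_foldchange(cbind(ref, q2), c("r1", "r2"))
  expect_equal(unname(fc2$q2$log2fc[1]), 1, tolerance = 0.05)
  expect_lt(max(abs(fc2$q2$log2fc[-1])), 0.05)
  expect_error(query_foldchange(cbind(ref, q2), "r1"), "at least 2")
})

test_that("stage assignment picks the matching signature and breaks ties early", {
  genes <- sprintf("h%02d", 1:30)
  sig16 <- mk_sig(16, stats::setNames(c(rep(3, 10), rep(-1, 20)), genes))
  sig27 <- mk_sig(27, stats::setNames(c(rep(-1, 20), rep(3, 10)), genes))
  qv <- structure(list(sample_id = "q1",
                       log2fc = sig16$log2fc + rnorm(30, 0, 0.05),
                       n_reference = 2), class = "query_foldchange")
  st <- stage_queries(list(sig16, sig27), list(qv), min_genes = 5)
  expect_equal(st$assignments$assigned_stage_hr, 16)
  expect_equal(st$assignments$coarse_label, "mid")
  expect_true(all(abs(st$rho[is.finite(st$rho)]) <= 1))
  # identical signatures at two hours -> equal rho -> earliest hour wins
  sig_a <- mk_sig(1, sig16$log2fc)
  sig_b <- mk_sig(36, sig16$log2fc)
  st2 <- stage_queries(list(sig_b, sig_a), list(qv), min_genes = 5)
  expect_equal(st2$assignments$assigned_stage_hr, 1)
  expect_equal(st2$assignments$coarse_label, "early")
  # insufficient overlap -> NaN cell with warning, excluded from argmax
  sig_small <- mk_sig(48, stats::setNames(rep(2, 4), paste0("x", 1:4)))
  expect_warning(st3 <- stage_queries(list(sig16, sig_small), list(qv),
                                      min_genes = 10),
                 "overlapping genes")
  expect_true(is.nan(st3$rho[1, "48"]))
  expect_equal(st3$assignments$assigned_stage_hr, 16)
})

test_that("staging is invariant to query depth and deterministic end to end", {
  sim <- simulate_timecourse(small_config(seed = 17))
  grp <- as.character(sim$meta$timepoint_hr)
  sigs <- suppressWarnings(timepoint_signatures(sim$counts, grp))
  bulk <- simulate_query_bulk(sim$truth, n_queries_per_stage = 2,
                              n_references = 3, noise_sd = 0, seed = 5)
  refs <- bulk$meta$sample_id[bulk$meta$is_reference]
  qfc <- query_foldchange(bulk$counts, refs)
  st <- stage_queries(sigs, qfc)
  truth <- bulk$meta$true_stage_hr[match(st$assignments$sample_id,
                                         bulk$meta$sample_id)]
  expect_equal(st$assignments$assigned_stage_hr, truth)  # noiseless: exact
  # global rescaling of a query's library leaves its correlations unchanged
  scaled <- bulk$counts
  scaled[, !bulk$meta$is_reference] <- scaled[, !bulk$meta$is_reference] * 4L
  st2 <- stage_queries(sigs, query_foldchange(scaled, refs))
  expect_equal(st$rho, st2$rho, tolerance = 1e-6)
  # identical inputs give identical StagingMatrix
  st3 <- stage_queries(sigs, qfc)
  expect_identical(st$rho, st3$rho)
  expect_identical(st$assignments, st3$assignments)
})

test_that("severity association detects a planted monotone relationship", {
  genes <- sprintf("h%02d", 1:30)
  base <- stats::setNames(c(rep(3, 10), rep(-1, 20)), genes)
  sigs <- list(mk_sig(1, base),
               mk_sig(16, stats::setNames(sample(base), genes)),
               mk_sig(48, stats::setNames(sample(base), genes)))
  queries <- lapply(1:12, function(i) {
    tp <- c(1, 16, 48)[(i - 1) %% 3 + 1]
    structure(list(sample_id = sprintf("q%02d", i),
                   log2fc = sigs[[match(tp, c(1, 16, 48))]]$log2fc +
                     rnorm(30, 0, 0.1),
                   n_reference = 2), class = "query_foldchange")
  })
  st <- stage_queries(sigs, queries, min_genes = 5)
  # severity strictly decreasing in assigned stage -> rho = -1
  rk <- match(st$assignments$assigned_stage_hr, c(1, 16, 48))
  sev <- data.frame(sample_id = st$assignments$sample_id,
                    sofa = 20 - 3 * rk)
  assoc <- severity_association(st, sev, n_perm = 2000, seed = 1)
  expect_equal(unname(assoc$estimate), -1)
  expect_lt(assoc$p.value, 0.05)
  expect_s3_class(assoc, "htest")
  expect_error(severity_association(st, sev[1:3, ]), "fewer than 4")
})
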