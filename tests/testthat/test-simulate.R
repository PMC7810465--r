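test_that("simulation is a pure function of config and seed", {
  cfg <- small_config(seed = 5)
  a <- simulate_timecourse(cfg)
  b <- simulate_timecourse(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$meta, b$meta)
  expect_identical(a$truth$programs, b$truth$programs)
  c2 <- simulate_timecourse(small_config(seed = 6))
  expect_false(identical(a$counts, c2$counts))

  # simulation must not disturb the session RNG
  set.seed(123); before <- runif(3)
  set.seed(123); invisible(simulate_timecourse(cfg)); after <- runif(3)
  expect_identical(before, after)
})

test_that("simulated structure honors the config invariants", {
  cfg <- small_config(seed = 2)
  sim <- simulate_timecourse(cfg)
  expect_equal(dim(sim$counts),
               c(cfg$n_genes, cfg$n_cells_per_timepoint * length(cfg$timepoints)))
  sig <- sim$truth$signature_genes
  expect_equal(length(sig), length(cfg$timepoints))
  all_sig <- unlist(sig)
  expect_equal(anyDuplicated(all_sig), 0L)  # disjoint across time points
  expect_true(all(all_sig %in% rownames(sim$counts)))
  expect_true(all(sim$meta$mito_percent >= 0 & sim$meta$mito_percent <= 100))
  expect_identical(sim$meta$cell_id, colnames(sim$counts))
  # planted effect visible in raw group means
  tp <- as.character(cfg$timepoints[3])
  in_tp <- sim$meta$timepoint_hr == cfg$timepoints[3]
  g <- sig[[tp]]
  ratio <- rowMeans(sim$counts[g, in_tp]) / rowMeans(sim$counts[g, !in_tp])
  expect_gt(median(ratio), 2^(cfg$signature_log2fc - 1))
})

test_that("invalid simulator configurations are rejected", {
  expect_error(sim_config(n_genes = 0), "n_genes")
  expect_error(sim_config(nb_dispersion = 0), "nb_dispersion")
  expect_error(sim_config(signature_log2fc = -1), "signature_log2fc")
  expect_error(sim_config(timepoints = c(4, 1)), "increasing")
  expect_error(sim_config(n_genes = 50), "signature genes")
  expect_error(sim_config(mito_fraction_range = c(0.5, 1.5)), "mito_fraction_range")
})

test_that("null simulations yield chance-level discoveries", {
  disc <- vapply(1:5, function(r) {
    cfg <- sim_config(n_genes = 500, n_cells_per_timepoint = 60,
                      n_signature_genes_per_timepoint = 10,
                      signature_log2fc = 0, mean_library_size = 2000,
                      seed = 100 + r)
    sim <- simulate_timecourse(cfg)
    grp <- as.character(sim$meta$timepoint_hr)
    res <- nb_test(sim$counts, grp, "16")
    nrow(significant_genes(res, q = 0.05))
  }, numeric(1))
  expect_lte(mean(disc), 0.05 * 500)
})

test_that("planted signatures are recovered end to end", {
  sim <- simulate_timecourse(small_config(seed = 31))
  grp <- as.character(sim$meta$timepoint_hr)
  norm <- tmm_factors(sim$counts)
  disp <- estimate_dispersion(sim$counts, grp, norm)
  rec <- vapply(names(sim$truth$signature_genes), function(tp) {
    sig <- significant_genes(nb_test(sim$counts, grp, tp, norm, disp))
    mean(sim$truth$signature_genes[[tp]] %in% sig$gene_id)
  }, numeric(1))
  expect_true(all(rec >= 0.9))
})

test_that("bulk query generation is deterministic and checks its inputs", {
  sim <- simulate_timecourse(small_config(seed = 3))
  a <- simulate_query_bulk(sim$truth, n_queries_per_stage = 2,
                           n_references = 3, noise_sd = 0.1, seed = 7)
  b <- simulate_query_bulk(sim$truth, n_queries_per_stage = 2,
                           n_references = 3, noise_sd = 0.1, seed = 7)
  expect_identical(a$counts, b$counts)
  expect_identical(a$meta, b$meta)
  expect_error(simulate_query_bulk(sim$truth, 2, n_references = 1),
               "n_references")
  # boundary: references only
  refs <- simulate_query_bulk(sim$truth, n_queries_per_stage = 0,
                              n_references = 2, seed = 1)
  expect_equal(ncol(refs$counts), 2)
  expect_true(all(refs$meta$is_reference))
})

test_that("orthologue map construction matches its requested composition", {
  genes <- sprintf("g%03d", 1:200)
  # bijective case
  m1 <- make_orthologue_map(genes, frac_one_to_one = 1, frac_unmapped = 0,
                            seed = 1)
  expect_equal(nrow(m1), 200)
  expect_equal(anyDuplicated(m1$mouse), 0L)
  expect_equal(anyDuplicated(m1$human), 0L)
  # fully unmapped -> empty map, downstream translation errors
  m0 <- make_orthologue_map(genes, frac_one_to_one = 0, frac_unmapped = 1,
                            seed = 1)
  expect_equal(nrow(m0), 0)
  sig <- structure(list(timepoint_hr = 4, genes = genes[1:5],
                        log2fc = stats::setNames(rep(1, 5), genes[1:5])),
                   class = "timepoint_signature")
  expect_error(translate_signature(sig, m0), "no orthologues")
  # mixed case: counts match the construction
  m <- make_orthologue_map(genes, frac_one_to_one = 0.8, frac_unmapped = 0.1,
                           seed = 2)
  mapped <- unique(m$mouse)
  expect_equal(length(setdiff(genes, mapped)), 20)      # 10% unmapped
  tab <- table(m$mouse)
  expect_equal(sum(tab == 1), 160)                      # 80% one-to-one
  expect_equal(sum(tab == 2), 20)                       # rest one-to-many
  expect_error(make_orthologue_map(genes, 0.8, 0.5), "<= 1")
})

test_that("severity generator plants the requested stage relationship", {
  stages <- stats::setNames(rep(c(1, 4, 16, 27, 36, 48), each = 4),
                            sprintf("s%02d", 1:24))
  flat <- simulate_severity(stages, slope = 0, noise_sd = 0, seed = 1)
  expect_equal(length(unique(flat$sofa)), 1L)
  dec <- simulate_severity(stages, slope = -2, noise_sd = 0, seed = 1)
  ord <- dec$sofa[match(names(stages), dec$sample_id)]
  expect_true(all(diff(ord[order(stages)]) <= 0))
  expect_true(all(dec$sofa >= 0 & dec$sofa <= 24))
  # Monte-Carlo: negative rank correlation in nearly all seeds
  stages7 <- stats::setNames(rep(c(0, 1, 4, 16, 27, 36, 48), each = 4),
                             sprintf("q%02d", 1:28))
  hit <- vapply(1:100, function(s) {
    sev <- simulate_severity(stages7, slope = -2, noise_sd = 1, seed = s)
    rk <- match(stages7[sev$sample_id], sort(unique(stages7)))
    spearman_rho(rk, sev$sofa) < 0
  }, logical(1))
  expect_gte(mean(hit), 0.95)
})
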