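# Shared fixture: a small on-disk synthetic bundle plus its run_config.

write_small_bundle <- function(dir, seed = 21) {
  cfg <- small_config(seed = seed)
  sim <- simulate_timecourse(cfg)
  omap <- make_orthologue_map(rownames(sim$counts), 0.8, 0.1, seed = seed)
  bulk <- simulate_query_bulk(sim$truth, n_queries_per_stage = 2,
                              n_references = 3, noise_sd = 0.1, seed = seed,
                              ortho_map = omap)
  truth_stage <- stats::setNames(bulk$meta$true_stage_hr, bulk$meta$sample_id)
  sev <- simulate_severity(truth_stage[!is.na(truth_stage)], slope = -2,
                           noise_sd = 1, seed = seed)
  suppressMessages(write_sim_bundle(sim, bulk, omap, sev, dir))
  list(sim = sim, bulk = bulk)
}

bundle_config <- function(dir, outdir, n_subsample = 60) {
  run_config(counts = file.path(dir, "sc_counts"),
             cell_metadata = file.path(dir, "cell_metadata.tsv"),
             query_counts = file.path(dir, "query_counts.tsv"),
             sample_metadata = file.path(dir, "sample_metadata.tsv"),
             orthologues = file.path(dir, "orthologues.tsv"),
             severity = file.path(dir, "severity.tsv"),
             outdir = outdir, min_genes = 50, max_genes = 3000,
             n_subsample = n_subsample, seed = 999)
}
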