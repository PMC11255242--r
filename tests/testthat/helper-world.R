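# shared simulated worlds, built once per test run
.world_cache <- new.env(parent = emptyenv())

# moderate peak-arm world used across peakcall / seqfeat / rloopclf tests
small_world <- function() {
  if (!is.null(.world_cache$small)) return(.world_cache$small)
  prof <- species_profile("human_like", n_genes = 60)
  cfg <- simulation_config(seed = 424242)
  pl <- plant_motifs(simulate_genome(prof, seed = 424242), cfg)
  w <- list(bundle = pl$bundle, truth = pl$truth, cfg = cfg,
            cov_ctrl = simulate_coverage(pl$bundle, pl$truth, "control", cfg),
            cov_kd = simulate_coverage(pl$bundle, pl$truth, "kd", cfg))
  w$pk_ctrl <- call_peaks(w$cov_ctrl)
  w$pk_kd <- call_peaks(w$cov_kd)
  .world_cache$small <- w
  w
}
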