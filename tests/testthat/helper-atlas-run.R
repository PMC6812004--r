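# One full two-pass pipeline run on the default atlas, shared by the
# recovery tests (cluster count, subclusters, composition).  Computed once
# per test session.
atlas_cache <- new.env(parent = emptyenv())

atlas_run <- function(seed = 101) {
  key <- paste0("run", seed)
  if (is.null(atlas_cache[[key]])) {
    cfg <- eec_pipeline_config(
      generator = eec_atlas_config(n_cells = 1500, seed = seed), seed = seed)
    atlas_cache[[key]] <- run_pipeline(cfg)
  }
  atlas_cache[[key]]
}
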