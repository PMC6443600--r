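# One full default pipeline run (96 chemotherapy + 14 TKI patients,
# 592-feature bank) shared by the end-to-end checks; memoised so the
# suite pays its cost once.
.run_cache <- new.env(parent = emptyenv())

full_default_run <- function() {
  if (is.null(.run_cache$report)) {
    t0 <- proc.time()
    cfg <- run_config(seed = 20260921)
    .run_cache$report <- suppressWarnings(run_pipeline(cfg))
    .run_cache$elapsed <- unname((proc.time() - t0)["elapsed"])
  }
  list(report = .run_cache$report, elapsed = .run_cache$elapsed)
}
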