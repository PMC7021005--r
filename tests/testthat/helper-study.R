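# The default study is expensive, so the acceptance tests share one run,
# computed lazily on first use.
.study_cache <- new.env(parent = emptyenv())

default_study <- function() {
  if (is.null(.study_cache$res)) {
    cfg <- study_config(master_seed = 1L)
    t0 <- proc.time()
    res <- run_study(cfg, verbose = FALSE)
    .study_cache$elapsed_s <- (proc.time() - t0)[["elapsed"]]
    .study_cache$res <- res
    .study_cache$config <- cfg
  }
  list(res = .study_cache$res, config = .study_cache$config,
       elapsed_s = .study_cache$elapsed_s)
}
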