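# Memoised full-length scenario runs at default settings, shared between the
# long-running acceptance checks so each 4.5 h simulation is done once.
.run_cache <- new.env(parent = emptyenv())

cached_run <- function(scenario) {
  if (!exists(scenario, envir = .run_cache)) {
    cfg <- default_config()
    cfg$schedule$scenario <- scenario
    assign(scenario, run_drying(cfg, quiet = TRUE), envir = .run_cache)
  }
  get(scenario, envir = .run_cache)
}
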