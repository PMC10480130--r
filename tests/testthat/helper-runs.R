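# Transport runs shared across test files, computed once per test session.
# The full-scale runs use the study conditions: pencil beam, 10 cm x 5 cm
# diameter tissue cylinder, 0.25 cm bins, 2e5 histories.

.run_cache <- new.env(parent = emptyenv())

cached_run <- function(key, expr) {
  if (is.null(.run_cache[[key]])) assign(key, force(expr), envir = .run_cache)
  .run_cache[[key]]
}

full_run <- function(preset_name, seed = 424242) {
  cached_run(paste0(preset_name, "-", seed),
             run_scenario(preset(preset_name), histories = 2e5, seed = seed))
}

ci_run <- function(preset_name, seed = 424242) {
  cached_run(paste0("ci-", preset_name, "-", seed),
             run_scenario(preset(preset_name), histories = 1e4, seed = seed))
}
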