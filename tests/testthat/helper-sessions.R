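# Cached simulated sessions shared across test files (built once per run).
.session_cache <- new.env(parent = emptyenv())

cached_session <- function(name, cfg) {
  if (is.null(.session_cache[[name]]))
    .session_cache[[name]] <- simulate_session(cfg)
  .session_cache[[name]]
}

# mixed-population switch session used by most recovery tests
small_switch_session <- function(seed = 101) {
  cached_session(
    paste0("small-", seed),
    sim_config(population = c(TR = 12, RR = 12, appearing = 4,
                              disappearing = 4, random_remap = 4,
                              untuned = 6),
               n_trials = 60, switch_trial = 30, seed = seed))
}

cached_place_cells <- function(session, name, n_shuffles = 50) {
  key <- paste0("pc-", name)
  if (is.null(.session_cache[[key]]))
    .session_cache[[key]] <- find_place_cells(session, n_shuffles = n_shuffles)
  .session_cache[[key]]
}
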