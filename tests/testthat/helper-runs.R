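# Shared simulation fixtures, computed lazily once per test session.

.run_cache <- new.env(parent = emptyenv())

# default-configuration full-horizon run at a fixed seed
default_run <- function(seed = 1) {
  key <- paste0("full_", seed)
  if (is.null(.run_cache[[key]])) {
    .run_cache[[key]] <- allosim(allosim_config(), seed = seed)
  }
  .run_cache[[key]]
}

# the multi-seed batch used by the stochastic acceptance checks
default_batch <- function(seeds = 1:10) {
  key <- paste0("batch_", paste(seeds, collapse = "_"))
  if (is.null(.run_cache[[key]])) {
    .run_cache[[key]] <- lapply(seeds, function(s) {
      allosim(allosim_config(), seed = s)
    })
  }
  .run_cache[[key]]
}

# short event-logged run for conservation / event-structure checks
logged_run <- function(seed = 11, years = 3) {
  key <- paste0("log_", seed, "_", years)
  if (is.null(.run_cache[[key]])) {
    .run_cache[[key]] <- allosim(
      allosim_config(years = years, log_events = TRUE), seed = seed)
  }
  .run_cache[[key]]
}

# published reference tabulation of lifetime reproductive success
reference_bins <- function() {
  path <- system.file("extdata", "reference_lrs_bins.csv",
                      package = "allosim")
  utils::read.csv(path)
}
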