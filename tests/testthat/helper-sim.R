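# Shared simulation fixtures, generated once per test run and memoized.
.fixtures <- new.env(parent = emptyenv())

# Desk-scale default dataset (the generator's study conditions), written to
# a per-session temp dir. Used by the end-to-end and acceptance tests.
default_sim <- function() {
  if (is.null(.fixtures$default)) {
    dir <- file.path(tempdir(), "peakarch_default_sim")
    .fixtures$default <- simulate_dataset(sim_params(seed = 101L), dir)
  }
  .fixtures$default
}

# Small simulation, generated once, for pipeline and determinism tests.
small_run <- function() {
  if (is.null(.fixtures$small_run)) {
    dir <- file.path(tempdir(), "peakarch_small_sim")
    .fixtures$small_run <- simulate_dataset(small_params(seed = 51L), dir)
  }
  .fixtures$small_run
}

# Small, fast simulation parameters for unit tests of the generator itself.
small_params <- function(seed = 11L, ...) {
  sim_params(seed = seed, n_chroms = 1L, chrom_length = 1.2e6, n_genes = 80L,
             tissues = c("wing", "eye"), n_background_peaks = 20L,
             n_blacklist = 2L, n_repeats = 2L, ...)
}
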