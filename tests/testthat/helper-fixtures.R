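# Small shared fixtures. The full-size simulation is expensive enough
# to build once per test run.

tiny_config <- function(seed = 7, ...) {
  args <- list(seed = seed, n_samples = 60, n_snps = 400,
               mito_length = 3000, n_nuclear_seqs = 3,
               nuclear_length = 1200)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

tiny_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_dataset(tiny_config())
    cache
  }
})

# deterministic toy reference set used across probe-selection tests
toy_refs <- function() {
  set.seed(101)
  reference_set(mito = paste(sample(c("A", "C", "G", "T"), 400,
                                    replace = TRUE), collapse = ""),
                nuclear = c(n1 = paste(sample(c("A", "C", "G", "T"), 300,
                                              replace = TRUE), collapse = ""),
                            n2 = paste(sample(c("A", "C", "G", "T"), 250,
                                              replace = TRUE), collapse = "")))
}

substr_of <- function(s, from, len) substr(s, from, from + len - 1)
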